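## Plain-text readers and writers for all pipeline artifacts. Expression,
## sample sheets, presence calls, DE tables, SNPs and GO annotations are TSV;
## features are GTF (1-based, via rtracklayer); marks are BED6 (0-based
## half-open on disk, converted by rtracklayer).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read/write an expression matrix with its sample sheet
#'
#' The expression TSV has a `feature_id` column plus one column per sample;
#' the sample sheet TSV has columns `sample`, `group`, `replicate`,
#' `platform`, `kind`.
#'
#' @param em an [expression_matrix()].
#' @param expr_path,samples_path file paths.
#' @return `write_expression_tsv` returns the paths invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(em, expr_path, samples_path = NULL) {
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expr_path)
  if (!is.null(samples_path)) {
    sheet <- cbind(em$design, platform = em$platform, kind = em$kind)
    write_tsv(sheet, samples_path)
  }
  invisible(c(expr_path, samples_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(expr_path, samples_path) {
  df <- read_tsv(expr_path)
  sheet <- read_tsv(samples_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$feature_id
  expression_matrix(values, sheet[, c("sample", "group", "replicate")],
                    platform = sheet$platform[1], kind = sheet$kind[1])
}

#' Read/write presence calls
#'
#' @param calls logical feature x group matrix.
#' @param path file path.
#' @export
write_presence_tsv <- function(calls, path) {
  write_tsv(data.frame(feature_id = rownames(calls), calls,
                       check.names = FALSE), path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE]) == "TRUE" | df[, -1, drop = FALSE] == TRUE
  rownames(m) <- df$feature_id
  m
}

#' Read/write DE tables
#'
#' @param table a `DETable` data.frame.
#' @param path file path.
#' @export
write_de_tsv <- function(table, path) write_tsv(table, path)

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) read_tsv(path)

#' Write/read genomic features as GENCODE-style GTF
#'
#' One `gene` line per feature with attributes `gene_id`, `gene_name` and
#' `gene_type`; coordinates 1-based inclusive on disk (GTF convention).
#'
#' @param features GRanges with mcols `id`, `biotype`.
#' @param path file path.
#' @export
write_annotation_gtf <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr) <- NULL
  gr$source <- "thlineage"
  gr$type <- "gene"
  gr$gene_id <- features$id
  gr$gene_name <- features$id
  gr$gene_type <- features$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  out <- GenomicRanges::granges(gr)
  out$id <- gr$gene_id
  out$biotype <- gr$gene_type
  out$type <- ifelse(gr$gene_type == "protein_coding", "gene", "lncRNA")
  out
}

#' Write/read mark intervals as BED6
#'
#' The BED name field carries the lineage label; on disk the file is
#' 0-based half-open (BED convention, handled by rtracklayer).
#'
#' @param marks GRanges with mcol `lineage` (or `name`).
#' @param path file path.
#' @export
write_marks_bed <- function(marks, path) {
  gr <- GenomicRanges::granges(marks)
  gr$name <- marks$lineage %||% marks$name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @param lineage optional filter on the BED name field.
#' @export
read_marks_bed <- function(path, lineage = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(gr)
  out$lineage <- gr$name
  if (!is.null(lineage)) out <- out[out$lineage == lineage]
  out
}

#' Read/write the SNP table
#'
#' TSV with columns `chrom`, `pos`, `trait`, `pvalue`.
#'
#' @param snps SNP data.frame.
#' @param path file path.
#' @export
write_snp_tsv <- function(snps, path) write_tsv(snps, path)

#' @rdname write_snp_tsv
#' @export
read_snp_tsv <- function(path) read_tsv(path)

#' Read/write GO structures
#'
#' The DAG travels as a child-parent edge-list TSV (columns `child`,
#' `parent`), annotations as a gene-to-term TSV (columns `gene_id`,
#' `term_id`). `read_go_obo()` additionally accepts a minimal OBO file
#' (only `id:` and `is_a:` tags are interpreted).
#'
#' @param dag a `GODag`.
#' @param path file path.
#' @export
write_go_edges_tsv <- function(dag, path) {
  edges <- do.call(rbind, lapply(dag$terms, function(t) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) return(NULL)
    data.frame(child = t, parent = ps, stringsAsFactors = FALSE)
  }))
  write_tsv(edges, path)
}

#' @rdname write_go_edges_tsv
#' @export
read_go_edges_tsv <- function(path) build_go_dag(read_tsv(path))

#' @rdname write_go_edges_tsv
#' @export
read_go_obo <- function(path) {
  lines <- readLines(path)
  cur <- NA_character_
  children <- parents <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "[Term]")) cur <- NA_character_
    else if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "is_a:") && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      children <- c(children, cur); parents <- c(parents, p)
    }
  }
  build_go_dag(data.frame(child = children, parent = parents,
                          stringsAsFactors = FALSE))
}

#' @rdname write_go_edges_tsv
#' @param gene2term annotation data.frame (`gene_id`, `term_id`).
#' @export
write_gene2term_tsv <- function(gene2term, path) write_tsv(gene2term, path)

#' @rdname write_go_edges_tsv
#' @export
read_gene2term_tsv <- function(path) read_tsv(path)
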