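## lncRNA characterization: biotype tally, lncRNA-mRNA co-expression network
## (|Pearson r| > 0.9), guilt-by-association GO attribution, and the
## expression trend of vicinity lncRNA-gene pairs.

GENCODE_LNC_BIOTYPES <- c("antisense", "lincRNA", "processed_transcript",
                          "sense_intronic", "sense_overlapping",
                          "3prime_overlapping_ncRNA")

#' Tally lncRNA biotypes
#'
#' Counts lncRNAs per GENCODE-style biotype (antisense, lincRNA/intergenic,
#' processed transcript, sense intronic, sense overlapping, 3' overlapping);
#' any other biotype is grouped as `"other"`.
#'
#' @param lnc_ids character vector of lncRNA ids (may be empty).
#' @param annotation GRanges with mcols `id`, `biotype`.
#' @return data.frame `biotype`, `n`, sorted by decreasing count.
#' @export
classify_biotype <- function(lnc_ids, annotation) {
  if (length(lnc_ids) == 0L)
    return(data.frame(biotype = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  bt <- annotation$biotype[match(lnc_ids, annotation$id)]
  if (any(is.na(bt)))
    stop_validation("lncRNA id(s) missing from annotation: ",
                    paste(utils::head(lnc_ids[is.na(bt)], 3), collapse = ", "))
  bt[!bt %in% GENCODE_LNC_BIOTYPES] <- "other"
  tab <- table(bt)
  out <- data.frame(biotype = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$biotype), , drop = FALSE]
}

#' lncRNA-gene co-expression network
#'
#' Pairs every lncRNA with every protein-coding gene whose expression
#' profiles have absolute Pearson correlation strictly above `threshold`
#' across the shared samples. Constant-expression features have undefined
#' correlation and contribute no edges (with a warning).
#'
#' @param lnc_expr,gene_expr numeric matrices (features x samples) on a
#'   common expression scale sharing sample columns; at least 3 shared
#'   samples are required.
#' @param threshold absolute-correlation cutoff (default 0.9, strict).
#' @return data.frame of edges: `lncrna_id`, `gene_id`, `r`, `n_samples`.
#' @export
coexpression_network <- function(lnc_expr, gene_expr, threshold = 0.9) {
  shared <- intersect(colnames(lnc_expr), colnames(gene_expr))
  if (length(shared) < 3L)
    stop_validation("need at least 3 shared samples, got ", length(shared))
  lnc <- lnc_expr[, shared, drop = FALSE]
  gen <- gene_expr[, shared, drop = FALSE]
  const_l <- apply(lnc, 1, stats::sd) == 0
  const_g <- apply(gen, 1, stats::sd) == 0
  if (any(const_l) || any(const_g))
    warning(sum(const_l) + sum(const_g),
            " constant-expression feature(s) excluded from the network")
  lnc <- lnc[!const_l, , drop = FALSE]
  gen <- gen[!const_g, , drop = FALSE]
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      r = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(lnc) == 0L || nrow(gen) == 0L) return(empty)
  r <- stats::cor(t(lnc), t(gen))
  idx <- which(abs(r) > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(lncrna_id = rownames(lnc)[idx[, 1]],
                    gene_id = rownames(gen)[idx[, 2]],
                    r = r[idx], n_samples = length(shared),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute enriched GO terms to lncRNAs (guilt by association)
#'
#' For each lncRNA, its study set is the protein-coding genes it is
#' co-expressed with; GO enrichment of that set against the universe is
#' computed and terms with p strictly below `cutoff` (raw, unadjusted) are
#' attributed to the lncRNA.
#'
#' @param edges co-expression edges from [coexpression_network()].
#' @param gene2term,dag GO annotations and DAG (see [go_enrichment()]).
#' @param universe character vector of protein-coding gene ids.
#' @param algorithm `"elim"` (default) or `"classic"`.
#' @param cutoff attribution p-value cutoff (default 0.01).
#' @param alpha_elim,min_term_size passed to [go_enrichment()].
#' @return data.frame: `lncrna_id`, `term_id`, `pvalue`, `algorithm`.
#' @export
attribute_terms_to_lncrnas <- function(edges, gene2term, dag, universe,
                                       algorithm = c("elim", "classic"),
                                       cutoff = 0.01, alpha_elim = cutoff,
                                       min_term_size = 3L) {
  algorithm <- match.arg(algorithm)
  term2genes <- if (is.list(gene2term) && !is.data.frame(gene2term))
    gene2term else propagate_annotations(gene2term, dag)
  rows <- list()
  for (l in unique(edges$lncrna_id)) {
    study <- intersect(unique(edges$gene_id[edges$lncrna_id == l]), universe)
    if (length(study) == 0L) next
    enr <- go_enrichment(study, universe, term2genes, dag,
                         algorithm = algorithm, alpha_elim = alpha_elim,
                         min_term_size = min_term_size)
    hit <- enr[enr$pvalue < cutoff, , drop = FALSE]
    if (nrow(hit) > 0L)
      rows[[l]] <- data.frame(lncrna_id = l, term_id = hit$term_id,
                              pvalue = hit$pvalue, algorithm = algorithm,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lncrna_id = character(0), term_id = character(0),
                      pvalue = numeric(0), algorithm = character(0),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Expression trend of lncRNA-gene pairs
#'
#' Per-pair Pearson correlation across all samples, with summary statistics
#' quantifying the overall trend (vicinity pairs of the same lineage are
#' expected to correlate positively).
#'
#' @param pairs data.frame with columns `lncrna_id`, `gene_id`
#'   (e.g. from [lncrna_gene_vicinity()]).
#' @param lnc_expr,gene_expr expression matrices sharing sample columns.
#' @return list with `pairs` (the input plus an `r` column), `mean_r`,
#'   `fraction_positive`, `n_pairs`. Empty input gives `n_pairs = 0` and
#'   NA summaries.
#' @export
pair_correlation_trend <- function(pairs, lnc_expr, gene_expr) {
  if (nrow(pairs) == 0L)
    return(list(pairs = cbind(pairs, r = numeric(0)),
                mean_r = NA_real_, fraction_positive = NA_real_, n_pairs = 0L))
  shared <- intersect(colnames(lnc_expr), colnames(gene_expr))
  if (length(shared) < 3L)
    stop_validation("need at least 3 shared samples")
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    stats::cor(lnc_expr[pairs$lncrna_id[i], shared],
               gene_expr[pairs$gene_id[i], shared])
  }, numeric(1))
  list(pairs = cbind(pairs, r = r),
       mean_r = mean(r, na.rm = TRUE),
       fraction_positive = mean(r > 0, na.rm = TRUE),
       n_pairs = nrow(pairs))
}
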