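## Disease-SNP trait enrichment: filter SNPs by association p-value,
## associate them to genes within +-100 kb, and test per-trait enrichment of
## a lineage-specific set with the hypergeometric upper tail.

#' Filter SNPs by association p-value
#'
#' Excludes SNPs with association p strictly greater than `threshold`
#' (the genome-wide-suggestive cutoff 1e-5 by default); a SNP at exactly the
#' threshold is retained.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `trait`, `pvalue`.
#' @param threshold association p-value cutoff (default 1e-5).
#' @return the retained rows.
#' @export
filter_snps <- function(snps, threshold = 1e-5) {
  req <- c("chrom", "pos", "trait", "pvalue")
  if (!all(req %in% names(snps)))
    stop_validation("snps needs columns ", paste(req, collapse = ", "))
  assert_probability(snps$pvalue, "snp pvalue", open0 = TRUE)
  snps[snps$pvalue <= threshold, , drop = FALSE]
}

#' Associate genes with SNP traits by genomic distance
#'
#' A gene is associated with a SNP's trait when the SNP lies within `window`
#' bp of the gene body (distance 0 inside the body); the rule is symmetric
#' and strand-independent, and a gene hit by several SNPs of one trait
#' counts once.
#'
#' @param snps filtered SNP data.frame (see [filter_snps()]).
#' @param genes GRanges with mcol `id` (works equally for lncRNA features).
#' @param window association distance in bp (default 100000).
#' @return data.frame with columns `gene_id`, `trait` (unique pairs).
#' @export
associate_genes <- function(snps, genes, window = 100000) {
  empty <- data.frame(gene_id = character(0), trait = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || length(genes) == 0L) return(empty)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(GenomicRanges::start(genes) - window, 1),
                     GenomicRanges::end(genes) + window))
  ov <- GenomicRanges::findOverlaps(snp_gr, ext, ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty)
  out <- unique(data.frame(gene_id = genes$id[S4Vectors::subjectHits(ov)],
                           trait = snps$trait[S4Vectors::queryHits(ov)],
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_id, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric trait enrichment of a lineage-specific set
#'
#' For each trait: with N universe genes of which K are trait-associated,
#' and a lineage set of n genes of which k are trait-associated, the
#' enrichment p-value is the hypergeometric upper tail P(X >= k).
#'
#' @param lineage_set character vector of feature ids, subset of `universe`.
#' @param gene_traits gene-trait association pairs from [associate_genes()].
#' @param universe character vector of feature ids tested for lineage
#'   specificity (associations outside it are ignored).
#' @return data.frame sorted by p-value: `trait`, `k`, `n`, `K`, `N`,
#'   `pvalue`.
#' @export
trait_hypergeometric_test <- function(lineage_set, gene_traits, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_validation("empty universe")
  lineage_set <- unique(lineage_set)
  if (!all(lineage_set %in% universe))
    stop_validation("lineage set must be a subset of the universe")
  gt <- gene_traits[gene_traits$gene_id %in% universe, , drop = FALSE]
  n <- length(lineage_set); N <- length(universe)
  traits <- sort(unique(gt$trait))
  rows <- lapply(traits, function(tr) {
    assoc <- unique(gt$gene_id[gt$trait == tr])
    K <- length(assoc)
    k <- length(intersect(lineage_set, assoc))
    data.frame(trait = tr, k = k, n = n, K = K, N = N,
               pvalue = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trait = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$pvalue, out$trait), , drop = FALSE]
}
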