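## Window arithmetic, mark-overlap counting, the randomization enrichment
## test, and the lncRNA-gene vicinity rule.
##
## Features and marks are GRanges (1-based, closed intervals, the native R
## convention); BED input/output through rtracklayer keeps the on-disk
## 0-based half-open convention.

#' Build a GRanges of genomic features
#'
#' @param df data.frame with columns `id`, `chrom`, `start`, `end` (1-based,
#'   closed), `strand` (`+`/`-`/`*`), and optionally `biotype`, `type`.
#' @return GRanges with mcols `id`, `biotype`, `type`.
#' @export
genomic_features <- function(df) {
  if (any(df$start > df$end)) stop_validation("start must be <= end")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand %||% "*")
  gr$id <- df$id
  gr$biotype <- df$biotype %||% NA_character_
  gr$type <- df$type %||% NA_character_
  gr
}

## transcription start site (1-bp GRanges): start on +/unstranded, end on -
feature_tss <- function(features) {
  minus <- as.character(GenomicRanges::strand(features)) == "-"
  pos <- ifelse(minus, GenomicRanges::end(features),
                GenomicRanges::start(features))
  GenomicRanges::GRanges(GenomicRanges::seqnames(features),
                         IRanges::IRanges(pos, pos),
                         strand = GenomicRanges::strand(features))
}

#' Window around a feature's TSS or body
#'
#' For a `+`-strand feature, the window runs `upstream` bp to the left and
#' `downstream` bp to the right of the anchor (TSS, or gene body ends);
#' on the `-` strand the two distances are mirrored. Coordinates are clamped
#' at position 1. With `strand_aware = FALSE` (or for unstranded features,
#' with a warning when the window is asymmetric) the `+` orientation is used.
#'
#' @param features GRanges (e.g. from [genomic_features()]).
#' @param upstream,downstream non-negative window extents in bp.
#' @param anchor `"tss"` or `"body"`.
#' @param strand_aware mirror the window on `-`-strand features?
#' @return GRanges of windows, mcols carried over.
#' @export
feature_window <- function(features, upstream, downstream,
                           anchor = c("tss", "body"), strand_aware = TRUE) {
  anchor <- match.arg(anchor)
  if (upstream < 0 || downstream < 0)
    stop_validation("window extents must be non-negative")
  str <- as.character(GenomicRanges::strand(features))
  if (strand_aware && upstream != downstream && any(str == "*"))
    warning("unstranded feature(s) with asymmetric window: treated as '+'")
  minus <- strand_aware & str == "-"
  if (anchor == "tss") {
    t1 <- ifelse(str == "-", GenomicRanges::end(features),
                 GenomicRanges::start(features))
    left <- ifelse(minus, t1 - downstream, t1 - upstream)
    right <- ifelse(minus, t1 + upstream, t1 + downstream)
  } else {
    s <- GenomicRanges::start(features); e <- GenomicRanges::end(features)
    left <- ifelse(minus, s - downstream, s - upstream)
    right <- ifelse(minus, e + upstream, e + downstream)
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(features),
                                IRanges::IRanges(pmax(left, 1),
                                                 pmax(right, 1)),
                                strand = GenomicRanges::strand(features))
  S4Vectors::mcols(out) <- S4Vectors::mcols(features)
  out
}

#' Count marks overlapping the windows of a feature set
#'
#' Counts mark intervals overlapping (by at least 1 bp) the union of the
#' features' windows. With `dedup = TRUE` (default) a mark falling in the
#' windows of several features is counted once; with `dedup = FALSE` every
#' feature-mark overlap counts.
#'
#' @param features GRanges of features (empty set gives 0).
#' @param marks GRanges of mark intervals.
#' @inheritParams feature_window
#' @param dedup count each mark at most once?
#' @return integer overlap count.
#' @export
count_marks_near_set <- function(features, marks, upstream, downstream,
                                 anchor = "tss", strand_aware = FALSE,
                                 dedup = TRUE) {
  if (length(features) == 0L) return(0L)
  win <- feature_window(features, upstream, downstream, anchor, strand_aware)
  if (dedup) {
    sum(IRanges::overlapsAny(marks, win, ignore.strand = TRUE))
  } else {
    sum(GenomicRanges::countOverlaps(win, marks, ignore.strand = TRUE))
  }
}

#' Randomization test for mark enrichment around a feature set
#'
#' Observed statistic: number of distinct marks overlapping the windows of
#' the target set. Null: `n_iter` draws of `|target|` features sampled
#' uniformly without replacement from the universe excluding the target
#' ("anywhere else in the genome"), each scored the same way. The empirical
#' p-value is `(#\{null >= observed\} + 1) / (n_iter + 1)`, so it is never 0
#' and is floored at `1/(n_iter+1)`.
#'
#' @param target character ids (matched against `universe$id`) or GRanges
#'   subset of the universe.
#' @param universe GRanges of all candidate features (mcol `id`).
#' @param marks GRanges of mark intervals.
#' @inheritParams feature_window
#' @param n_iter number of random draws (default 10000).
#' @param seed RNG seed.
#' @param exclude_target sample the null from `universe \ target` (default)
#'   or from the whole universe.
#' @return An `EnrichmentResult`: list with `observed`, `null_counts`,
#'   `empirical_p`, `n_iter`, `n_target`, `seed`.
#' @export
randomization_enrichment <- function(target, universe, marks,
                                     upstream, downstream, anchor = "tss",
                                     strand_aware = FALSE,
                                     n_iter = 10000L, seed = NULL,
                                     exclude_target = TRUE) {
  if (n_iter < 1L) stop_validation("n_iter must be >= 1")
  if (inherits(target, "GRanges")) target <- target$id
  t_idx <- match(target, universe$id)
  if (any(is.na(t_idx)))
    stop_validation("target feature(s) not in universe: ",
                    paste(utils::head(target[is.na(t_idx)], 3), collapse = ", "))
  win <- feature_window(universe, upstream, downstream, anchor, strand_aware)
  hits <- GenomicRanges::findOverlaps(win, marks, ignore.strand = TRUE)
  by_feature <- split(S4Vectors::subjectHits(hits),
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_along(universe)))
  score <- function(idx)
    length(unique(unlist(by_feature[idx], use.names = FALSE)))
  observed <- score(t_idx)
  pool <- if (exclude_target) setdiff(seq_along(universe), t_idx)
          else seq_along(universe)
  k <- length(t_idx)
  if (length(pool) < k)
    stop_validation("universe minus target (", length(pool),
                    ") is smaller than the target set (", k, ")")
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) score(sample(pool, k)), integer(1))
  })
  structure(list(observed = observed, null_counts = null_counts,
                 empirical_p = (sum(null_counts >= observed) + 1) / (n_iter + 1),
                 n_iter = n_iter, n_target = k, seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(paste0("EnrichmentResult: observed = %d marks around %d ",
                     "features\nnull mean %.2f (sd %.2f), n_iter = %d, ",
                     "empirical p = %.4g\n"),
              x$observed, x$n_target, mean(x$null_counts),
              stats::sd(x$null_counts), x$n_iter, x$empirical_p))
  invisible(x)
}

#' lncRNA-gene vicinity pairs
#'
#' A lncRNA is in the vicinity of a gene when it overlaps the window running
#' `upstream` bp (default 5 kb) before the gene body to `downstream` bp
#' (default 30 kb) after it, oriented by the gene's strand. A lncRNA may pair
#' with several genes.
#'
#' @param lncrnas,genes GRanges with mcol `id`.
#' @param upstream,downstream vicinity extents in bp.
#' @param anchor window anchor on the gene (default `"body"`).
#' @param strand_aware orient the window by gene strand (default TRUE).
#' @return data.frame with columns `lncrna_id`, `gene_id`.
#' @export
lncrna_gene_vicinity <- function(lncrnas, genes, upstream = 5000,
                                 downstream = 30000, anchor = "body",
                                 strand_aware = TRUE) {
  if (length(lncrnas) == 0L || length(genes) == 0L)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  win <- feature_window(genes, upstream, downstream, anchor, strand_aware)
  ov <- GenomicRanges::findOverlaps(lncrnas, win, ignore.strand = TRUE)
  out <- data.frame(lncrna_id = lncrnas$id[S4Vectors::queryHits(ov)],
                    gene_id = genes$id[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  unique(out[order(out$lncrna_id, out$gene_id), , drop = FALSE])
}
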