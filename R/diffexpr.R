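## Differential expression.
##
## Reference two-group tests with the thresholds used throughout the
## pipeline: moderated t with empirical-Bayes variance shrinkage for
## intensity platforms, and the same statistic on variance-stabilized,
## median-of-ratios-normalized values for count platforms. A feature is
## differentially expressed when BH-adjusted p < 0.05 and |log2FC| > 1
## (both strict), optionally refined by present/absent calls.

comparison_label <- function(reference, test) paste0(reference, "_vs_", test)

parse_comparison <- function(label) {
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_validation("malformed comparison '", label, "'")
  c(reference = parts[1], test = parts[2])
}

#' Median-of-ratios size factors for a count matrix
#'
#' Per sample, the factor is the median over genes (positive in all samples)
#' of the ratio of that sample's count to the gene's geometric mean across
#' samples, rescaled so the factors have geometric mean exactly 1.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return numeric vector of positive size factors named by sample.
#' @export
median_of_ratios_size_factors <- function(counts) {
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  log_gm <- rowMeans(log(counts))        # -Inf for rows with any zero
  use <- is.finite(log_gm)
  if (!any(use))
    stop_validation("no gene has positive counts in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_gm[use]))
  })
  sf <- sf / exp(mean(log(sf)))          # geometric mean 1
  stats::setNames(sf, colnames(counts))
}

#' Variance-stabilizing reference transform for counts
#'
#' `log2(count / size_factor + 1)`: monotone in counts within each sample and
#' approximately log2-scale for well-expressed genes. This parameter-free
#' transform backs both the mixture presence calls and the count DE test.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param size_factors positive per-sample factors; computed by
#'   [median_of_ratios_size_factors()] if omitted.
#' @return numeric matrix of the same shape.
#' @export
variance_stabilize <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(counts)
  if (any(size_factors <= 0)) stop_validation("size factors must be positive")
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

## Moment-matching fit of the scaled-inverse-chi-square prior for gene-wise
## variances: under the hierarchical model s2 / s02 ~ F(df, d0), so
## E[log s2] and Var[log s2] identify (d0, s02) through digamma/trigamma.
fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) stop_validation("too few positive variances")
  z <- log(s2)
  ev <- stats::var(z) - trigamma(df / 2)
  if (ev > 0) {
    d0 <- min(2 * trigamma_inverse(ev), d0_cap)
  } else {
    d0 <- d0_cap
  }
  s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
               digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

## Newton inversion of the trigamma function (solve trigamma(y) = x, y > 0)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per feature, log2FC = mean(test) - mean(reference) and the pooled
#' two-sample variance s2 on df = n1 + n2 - 2 degrees of freedom. The prior
#' (d0, s02) is estimated by moment matching on the observed variance
#' distribution; the posterior variance (d0*s02 + df*s2) / (d0 + df) replaces
#' s2 in the t statistic, which gains d0 extra degrees of freedom.
#'
#' @param em an [expression_matrix()] on a roughly log2/Gaussian scale.
#' @param reference,test group labels of the comparison (log2FC is
#'   test minus reference).
#' @param d0,s02 optional overrides of the estimated prior: `d0 = 0` gives
#'   the ordinary equal-variance t-test, `d0 = Inf` (with `s02`) fully
#'   shrinks every feature to the common variance `s02`.
#' @return A `DETable` data.frame: `feature_id`, `comparison`, `log2fc`,
#'   `t`, `pvalue`, `adj_pvalue` (NA until [apply_de_filter()]), `is_de`
#'   (NA), `platform`; attributes `d0`, `s02`, `df`.
#' @export
moderated_t_test <- function(em, reference, test, d0 = NULL, s02 = NULL) {
  x_r <- em$values[, group_samples(em, reference), drop = FALSE]
  x_t <- em$values[, group_samples(em, test), drop = FALSE]
  n1 <- ncol(x_r); n2 <- ncol(x_t)
  if (n1 < 2L || n2 < 2L)
    stop_validation("need at least 2 replicates per group, got ",
                    n1, " and ", n2)
  df <- n1 + n2 - 2
  m_r <- rowMeans(x_r); m_t <- rowMeans(x_t)
  lfc <- m_t - m_r
  s2 <- (rowSums((x_r - m_r)^2) + rowSums((x_t - m_t)^2)) / df

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  } else if (is.null(s02)) {
    s02 <- if (d0 > 0) fit_variance_prior(s2, df)$s02 else 0
  }
  d0_eff <- min(d0, 1e6)                   # cap represents "infinite" shrinkage
  s2_post <- if (d0_eff == 0) s2
             else if (is.infinite(d0)) rep(s02, length(s2))
             else (d0_eff * s02 + df * s2) / (d0_eff + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df = df + d0_eff, lower.tail = FALSE)

  out <- data.frame(
    feature_id = rownames(em$values),
    comparison = comparison_label(reference, test),
    log2fc = unname(lfc), t = unname(tstat), pvalue = unname(p),
    adj_pvalue = NA_real_, is_de = NA,
    platform = em$platform, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0; attr(out, "s02") <- s02; attr(out, "df") <- df
  out
}

#' Count-platform DE test on variance-stabilized values
#'
#' Normalizes raw counts by median-of-ratios size factors, variance-stabilizes
#' them, and applies the moderated t-test; the reported log2FC is on the
#' stabilized scale (a "modified" fold change shrunk toward zero for
#' low counts).
#'
#' @param em an [expression_matrix()] of kind `"count"`.
#' @param reference,test group labels of the comparison.
#' @param size_factors optional precomputed size factors.
#' @inheritParams moderated_t_test
#' @return A `DETable` data.frame (see [moderated_t_test()]).
#' @export
count_de_test <- function(em, reference, test, size_factors = NULL,
                          d0 = NULL, s02 = NULL) {
  if (em$kind != "count") stop_validation("count_de_test needs a count matrix")
  if (is.null(size_factors))
    size_factors <- median_of_ratios_size_factors(em$values)
  vst <- expression_matrix(variance_stabilize(em$values, size_factors),
                           em$design, em$platform, "intensity")
  moderated_t_test(vst, reference, test, d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to `stats::p.adjust(method = "BH")`
#' after validating the input range).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length, clipped at 1.
#' @export
bh_adjust <- function(pvalues) {
  assert_probability(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the DE thresholds and presence refinement
#'
#' Marks a feature differentially expressed when BH-adjusted p < `alpha`
#' (strict) and |log2FC| > `lfc` (strict), and -- when presence calls are
#' supplied -- the feature is present under the chosen refinement rule.
#' Idempotent: reapplying with the same arguments does not change the table.
#'
#' @param table a `DETable` from [moderated_t_test()]/[count_de_test()].
#' @param presence optional logical feature x group matrix from the presence
#'   module, covering both compared groups.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param refine presence rule: `"either"` (default: present in at least one
#'   of the two compared groups), `"test"`, `"reference"`, `"both"`, or
#'   `"none"`.
#' @return the table with `adj_pvalue` and `is_de` filled in.
#' @export
apply_de_filter <- function(table, presence = NULL, alpha = 0.05, lfc = 1,
                            refine = c("either", "test", "reference",
                                       "both", "none")) {
  refine <- match.arg(refine)
  assert_probability(alpha, "alpha", open0 = TRUE)
  table$adj_pvalue <- bh_adjust(table$pvalue)
  de <- table$adj_pvalue < alpha & abs(table$log2fc) > lfc
  if (!is.null(presence) && refine != "none") {
    cmp <- parse_comparison(table$comparison[1])
    if (!all(cmp %in% colnames(presence)))
      stop_validation("presence matrix lacks group(s) ",
                      paste(setdiff(cmp, colnames(presence)), collapse = ", "))
    miss <- setdiff(table$feature_id, rownames(presence))
    if (length(miss) > 0)
      stop_validation(length(miss), " feature(s) missing from presence matrix")
    p_ref <- presence[table$feature_id, cmp["reference"]]
    p_tst <- presence[table$feature_id, cmp["test"]]
    ok <- switch(refine,
                 either = p_ref | p_tst,
                 test = p_tst,
                 reference = p_ref,
                 both = p_ref & p_tst)
    de <- de & ok
  }
  table$is_de <- unname(de)
  table
}
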