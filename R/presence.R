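## Present/absent calling.
##
## Expression of a feature in a sample subtype is accepted as genuine signal
## ("present") when, in every replicate of the subtype, the value is more
## likely to come from the higher-mean component of a two-component Gaussian
## mixture fitted to the pooled log2 expression values of the platform.
## Illumina-style arrays instead use the detection p-value rule
## (p < alpha in all replicates).

#' Fit a two-component Gaussian mixture by EM
#'
#' Fits `w_lo * N(mu_lo, sd_lo) + w_hi * N(mu_hi, sd_hi)` to a vector of
#' (log2-scale) expression values by expectation-maximization. The first start
#' initializes responsibilities by a median split; further starts split at a
#' random quantile, and the best final log-likelihood wins. Components are
#' returned ordered so that `mean_low < mean_high`.
#'
#' @param x numeric vector of at least 10 finite values with positive variance.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of restarts.
#' @param seed optional RNG seed for the restart initializations.
#' @param sd_floor lower bound on component standard deviations, preventing
#'   collapse onto a single point.
#' @return A `MixtureFit`: list with `mean_low`, `mean_high`, `sd_low`,
#'   `sd_high`, `weight_low`, `weight_high`, `loglik`, `loglik_trace`
#'   (non-decreasing within the winning run), `converged`, `n_iter`.
#' @export
fit_two_component_em <- function(x, tol = 1e-8, max_iter = 500L, n_starts = 5L,
                                 seed = NULL, sd_floor = 1e-3) {
  x <- x[is.finite(x)]
  if (length(x) < 10L)
    stop_validation("need at least 10 finite values to fit the mixture")
  if (stats::var(x) == 0)
    stop_validation("zero-variance input: mixture fit is degenerate")
  if (tol <= 0) stop_validation("tol must be positive")

  run_em <- function(resp_hi) {
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ## M step from current responsibilities
      w_hi <- mean(resp_hi)
      w_hi <- min(max(w_hi, 1e-6), 1 - 1e-6)
      w_lo <- 1 - w_hi
      s_hi <- sum(resp_hi); s_lo <- sum(1 - resp_hi)
      mu_hi <- sum(resp_hi * x) / s_hi
      mu_lo <- sum((1 - resp_hi) * x) / s_lo
      sd_hi <- max(sqrt(sum(resp_hi * (x - mu_hi)^2) / s_hi), sd_floor)
      sd_lo <- max(sqrt(sum((1 - resp_hi) * (x - mu_lo)^2) / s_lo), sd_floor)
      ## E step + log-likelihood (log-sum-exp)
      la <- log(w_lo) + stats::dnorm(x, mu_lo, sd_lo, log = TRUE)
      lb <- log(w_hi) + stats::dnorm(x, mu_hi, sd_hi, log = TRUE)
      m <- pmax(la, lb)
      lse <- m + log(exp(la - m) + exp(lb - m))
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp_hi <- exp(lb - lse)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) <= tol * (abs(ll_prev) + tol)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(mu = c(mu_lo, mu_hi), sd = c(sd_lo, sd_hi), w = c(w_lo, w_hi),
         loglik = ll, trace = trace, converged = converged,
         n_iter = length(trace))
  }

  fits <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      q <- if (i == 1L) 0.5 else stats::runif(1, 0.25, 0.75)
      run_em(as.numeric(x > stats::quantile(x, q)))
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations")
  ord <- order(best$mu)
  structure(list(
    mean_low = best$mu[ord[1]], mean_high = best$mu[ord[2]],
    sd_low = best$sd[ord[1]], sd_high = best$sd[ord[2]],
    weight_low = best$w[ord[1]], weight_high = best$w[ord[2]],
    loglik = best$loglik, loglik_trace = best$trace,
    restart_logliks = vapply(fits, `[[`, numeric(1), "loglik"),
    converged = best$converged, n_iter = best$n_iter,
    sd_floor = sd_floor
  ), class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(paste0("MixtureFit: low N(%.3f, %.3f) w=%.3f | ",
                     "high N(%.3f, %.3f) w=%.3f\n"),
              x$mean_low, x$sd_low, x$weight_low,
              x$mean_high, x$sd_high, x$weight_high))
  cat(sprintf("loglik %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Posterior probability of the high-mean mixture component
#'
#' @param fit a `MixtureFit`.
#' @param x numeric vector or matrix of values.
#' @param weighted if `TRUE` (default) the posterior responsibility
#'   (weights included); if `FALSE` the unweighted density comparison
#'   `d_high / (d_low + d_high)`.
#' @return numeric of the same shape as `x`, in (0, 1).
#' @export
posterior_high <- function(fit, x, weighted = TRUE) {
  lw_lo <- if (weighted) log(fit$weight_low) else 0
  lw_hi <- if (weighted) log(fit$weight_high) else 0
  la <- lw_lo + stats::dnorm(x, fit$mean_low, fit$sd_low, log = TRUE)
  lb <- lw_hi + stats::dnorm(x, fit$mean_high, fit$sd_high, log = TRUE)
  m <- pmax(la, lb)
  out <- exp(lb - (m + log(exp(la - m) + exp(lb - m))))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Mixture log-likelihood of data under a two-component fit
#'
#' Direct evaluation of the mixture density; used to verify the EM
#' monotonicity property independently of the EM internals.
#'
#' @param fit a `MixtureFit` (or list with the same fields).
#' @param x numeric vector.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(fit, x) {
  la <- log(fit$weight_low) + stats::dnorm(x, fit$mean_low, fit$sd_low, log = TRUE)
  lb <- log(fit$weight_high) + stats::dnorm(x, fit$mean_high, fit$sd_high, log = TRUE)
  m <- pmax(la, lb)
  sum(m + log(exp(la - m) + exp(lb - m)))
}

#' Present/absent calls from a mixture fit
#'
#' A feature is called present in a sample group when every replicate's value
#' favors the high-mean component.
#'
#' @param em an [expression_matrix()] whose pooled values produced `fit`
#'   (log2 intensities, or variance-stabilized counts).
#' @param fit a `MixtureFit`.
#' @param rule `"posterior"` (default: responsibility of the high component
#'   > 0.5, mixing weights included) or `"density"` (unweighted component
#'   density comparison).
#' @return A logical feature x group matrix (a `PresenceMatrix`).
#' @export
call_presence_mixture <- function(em, fit, rule = c("posterior", "density")) {
  rule <- match.arg(rule)
  p_hi <- posterior_high(fit, em$values, weighted = rule == "posterior")
  groups <- groups_of(em)
  calls <- matrix(FALSE, nrow(em$values), length(groups),
                  dimnames = list(rownames(em$values), groups))
  for (g in groups) {
    idx <- match(group_samples(em, g), colnames(em$values))
    calls[, g] <- rowSums(p_hi[, idx, drop = FALSE] > 0.5) == length(idx)
  }
  calls
}

#' Present/absent calls from detection p-values
#'
#' Illumina-array rule: present iff the detection p-value is strictly below
#' `alpha` in all replicates of the sample subtype.
#'
#' @param detection_p numeric feature x sample matrix of detection p-values
#'   in `[0, 1]`.
#' @param design sample design data.frame (columns `sample`, `group`).
#' @param alpha detection threshold, default 0.01.
#' @return logical feature x group matrix.
#' @export
call_presence_detection <- function(detection_p, design, alpha = 0.01) {
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE) ||
      any(is.na(detection_p)))
    stop_validation("detection p-values must lie in [0,1]")
  assert_probability(alpha, "alpha", open0 = TRUE)
  groups <- unique(design$group)
  calls <- matrix(FALSE, nrow(detection_p), length(groups),
                  dimnames = list(rownames(detection_p), groups))
  for (g in groups) {
    idx <- match(design$sample[design$group == g], colnames(detection_p))
    calls[, g] <- rowSums(detection_p[, idx, drop = FALSE] < alpha) == length(idx)
  }
  calls
}

#' Collapse duplicate probes to one row per gene by inter-quartile range
#'
#' Probes mapping to the same gene are collapsed by retaining the probe with
#' the largest IQR across all samples; unmapped probes are dropped. Exact IQR
#' ties go to the lexicographically smallest probe id (deterministic).
#'
#' @param em an [expression_matrix()].
#' @param feature_to_gene data.frame with columns `feature_id`, `gene_id`, or
#'   a character vector of gene ids named by feature id.
#' @return An `ExpressionMatrix` with one row per gene (rownames = gene ids).
#' @export
collapse_duplicates_by_iqr <- function(em, feature_to_gene) {
  if (is.character(feature_to_gene) && !is.null(names(feature_to_gene)))
    feature_to_gene <- data.frame(feature_id = names(feature_to_gene),
                                  gene_id = unname(feature_to_gene))
  if (nrow(feature_to_gene) == 0L)
    stop_validation("empty feature-to-gene mapping")
  map <- feature_to_gene[feature_to_gene$feature_id %in% rownames(em$values), ,
                         drop = FALSE]
  if (nrow(map) == 0L)
    stop_validation("mapping matches no feature in the matrix")
  iqr <- apply(em$values[map$feature_id, , drop = FALSE], 1, stats::IQR)
  ord <- order(map$gene_id, -iqr, map$feature_id)
  keep <- ord[!duplicated(map$gene_id[ord])]
  out <- em$values[map$feature_id[keep], , drop = FALSE]
  rownames(out) <- map$gene_id[keep]
  expression_matrix(out[order(rownames(out)), , drop = FALSE],
                    em$design, em$platform, em$kind)
}
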