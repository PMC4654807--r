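## Cross-platform consensus and lineage classification.
##
## A feature earns a confident (consensus) DE call for a comparison when it
## is differentially expressed on at least two platforms with the same fold
## change direction. A feature is Th1-specific when it is DE in Thp-vs-Th1
## only -- not in Thp-vs-Th0 (the activation control) and not in Thp-vs-Th2 --
## and symmetrically for Th2.

#' Cross-platform differential-expression consensus
#'
#' Combines per-platform `DETable`s: for each feature and comparison, the
#' consensus call is true when the feature is DE (`is_de`) on at least two
#' platforms and all DE platforms agree in log2FC sign. A feature absent from
#' a platform's table contributes no vote (platforms differ in annotation
#' coverage); a comparison missing from a platform produces a warning, not an
#' error.
#'
#' @param tables list of `DETable` data.frames (one per platform per
#'   comparison, after [apply_de_filter()]), or a single rbind-ed table.
#' @param min_platforms minimum number of agreeing DE platforms (default 2).
#' @return data.frame with one row per feature x comparison: `feature_id`,
#'   `comparison`, `n_de`, `consensus_de`, `consensus_sign` (+1/-1, NA when
#'   no consensus).
#' @export
build_consensus <- function(tables, min_platforms = 2L) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, lapply(tables, function(t) {
    t[, c("feature_id", "comparison", "log2fc", "is_de", "platform")]
  }))
  if (any(is.na(tab$is_de)))
    stop_validation("run apply_de_filter() before build_consensus()")
  platforms <- unique(tab$platform)
  if (length(platforms) < 2L)
    stop_validation("consensus needs DE tables from at least 2 platforms")
  for (p in platforms) {
    missing_cmp <- setdiff(unique(tab$comparison),
                           unique(tab$comparison[tab$platform == p]))
    if (length(missing_cmp) > 0)
      warning("platform '", p, "' contributes no vote for comparison(s) ",
              paste(missing_cmp, collapse = ", "))
  }
  key <- paste(tab$feature_id, tab$comparison, sep = "\r")
  de <- tab[tab$is_de, , drop = FALSE]
  de_key <- paste(de$feature_id, de$comparison, sep = "\r")
  n_de <- table(de_key)
  sign_ok <- tapply(sign(de$log2fc), de_key,
                    function(s) length(unique(s)) == 1L)
  sign_val <- tapply(sign(de$log2fc), de_key, function(s) s[1])

  uniq <- !duplicated(key)
  out <- data.frame(feature_id = tab$feature_id[uniq],
                    comparison = tab$comparison[uniq],
                    stringsAsFactors = FALSE)
  k <- paste(out$feature_id, out$comparison, sep = "\r")
  out$n_de <- as.integer(n_de[k]); out$n_de[is.na(out$n_de)] <- 0L
  cons <- out$n_de >= min_platforms & !is.na(sign_ok[k]) & sign_ok[k]
  cons[is.na(cons)] <- FALSE
  out$consensus_de <- unname(cons)
  out$consensus_sign <- ifelse(out$consensus_de, unname(sign_val[k]), NA_real_)
  rownames(out) <- NULL
  out[order(out$feature_id, out$comparison), , drop = FALSE]
}

## Wide DE-status view (features x comparisons), from either a consensus
## data.frame or a list of filtered single-platform DETables.
de_status_matrix <- function(x, comparisons) {
  if (is.data.frame(x) && "consensus_de" %in% names(x)) {
    feat <- unique(x$feature_id)
    de <- sgn <- matrix(NA, length(feat), length(comparisons),
                        dimnames = list(feat, comparisons))
    idx <- cbind(match(x$feature_id, feat), match(x$comparison, comparisons))
    keep <- !is.na(idx[, 2])
    de[idx[keep, , drop = FALSE]] <- x$consensus_de[keep]
    sgn[idx[keep, , drop = FALSE]] <- x$consensus_sign[keep]
  } else {
    if (is.data.frame(x)) x <- list(x)
    tab <- do.call(rbind, x)
    if (any(is.na(tab$is_de)))
      stop_validation("run apply_de_filter() before classification")
    feat <- unique(tab$feature_id)
    de <- sgn <- matrix(NA, length(feat), length(comparisons),
                        dimnames = list(feat, comparisons))
    idx <- cbind(match(tab$feature_id, feat),
                 match(tab$comparison, comparisons))
    keep <- !is.na(idx[, 2])
    de[idx[keep, , drop = FALSE]] <- tab$is_de[keep]
    sgn[idx[keep, , drop = FALSE]] <- sign(tab$log2fc)[keep]
  }
  absent <- colSums(!is.na(de)) == 0
  if (any(absent))
    stop_validation("no DE status for comparison(s): ",
                    paste(comparisons[absent], collapse = ", "))
  de[is.na(de)] <- FALSE
  list(de = de, sign = sgn)
}

#' Classify features as Th1-specific, Th2-specific, or neither
#'
#' Applies the lineage-specificity definition to DE status across the three
#' comparisons Thp-vs-Th0, Thp-vs-Th1, Thp-vs-Th2: a feature is Th1-specific
#' iff it is DE in Thp-vs-Th1 but in neither Thp-vs-Th0 nor Thp-vs-Th2
#' (symmetrically for Th2). Direction (up/down in the polarized lineage)
#' comes from the sign of the polarized comparison.
#'
#' @param x a consensus data.frame from [build_consensus()]
#'   (`mode = "consensus"`) or filtered `DETable`(s) from a single
#'   sequencing platform (`mode = "seqonly"`).
#' @param mode evidence mode recorded in the output.
#' @param reference,polarized,control group labels (defaults `Thp`,
#'   `c("Th1","Th2")`, `Th0`).
#' @return data.frame: `feature_id`, `label` (`"Th1-specific"`,
#'   `"Th2-specific"`, `"none"`), `direction` (`"up"`/`"down"`/NA),
#'   `evidence_mode`.
#' @export
classify_lineage <- function(x, mode = c("consensus", "seqonly"),
                             reference = "Thp",
                             polarized = c("Th1", "Th2"),
                             control = "Th0") {
  mode <- match.arg(mode)
  comparisons <- comparison_label(reference, c(control, polarized))
  st <- de_status_matrix(x, comparisons)
  c0 <- comparisons[1]; c1 <- comparisons[2]; c2 <- comparisons[3]
  th1 <- st$de[, c1] & !st$de[, c2] & !st$de[, c0]
  th2 <- st$de[, c2] & !st$de[, c1] & !st$de[, c0]
  label <- ifelse(th1, paste0(polarized[1], "-specific"),
                  ifelse(th2, paste0(polarized[2], "-specific"), "none"))
  sgn <- ifelse(th1, st$sign[, c1], ifelse(th2, st$sign[, c2], NA))
  data.frame(feature_id = rownames(st$de),
             label = unname(label),
             direction = unname(ifelse(is.na(sgn), NA_character_,
                                       ifelse(sgn > 0, "up", "down"))),
             evidence_mode = mode,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname classify_lineage
#' @param assignments result of [classify_lineage()].
#' @param label which label's feature ids to extract (e.g. `"Th1-specific"`).
#' @export
lineage_set <- function(assignments, label) {
  assignments$feature_id[assignments$label == label]
}
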