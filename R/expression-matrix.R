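#' Expression matrix with sample design
#'
#' Container used by all expression-based stages: a numeric features x samples
#' matrix together with a sample design (group and replicate per sample) and a
#' platform kind. Intensity platforms carry log2 intensities; count platforms
#' carry non-negative integer counts (variance-stabilized downstream).
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample ids.
#' @param design data.frame with columns `sample`, `group`, `replicate`;
#'   `design$sample` must match `colnames(values)`.
#' @param platform platform identifier (e.g. "affy", "rnaseq").
#' @param kind `"intensity"` or `"count"`.
#' @return An object of class `ExpressionMatrix` (list with elements
#'   `values`, `design`, `platform`, `kind`).
#' @export
expression_matrix <- function(values, design, platform = "platform",
                              kind = c("intensity", "count")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("values must have feature rownames and sample colnames")
  req <- c("sample", "group", "replicate")
  if (!all(req %in% names(design)))
    stop_validation("design must have columns sample, group, replicate")
  if (!setequal(design$sample, colnames(values)))
    stop_validation("design samples must match matrix columns")
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (kind == "intensity" && any(!is.finite(values)))
    stop_validation("intensity values must be finite")
  if (kind == "count" && any(values < 0 | values != round(values)))
    stop_validation("count values must be non-negative integers")
  if (any(table(design$group) < 1L))
    stop_validation("every group needs at least one replicate")
  structure(list(values = values, design = design,
                 platform = platform, kind = kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s' (%s): %d features x %d samples\n",
              x$platform, x$kind, nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s(n=%d)", names(table(x$design$group)),
                               table(x$design$group)), collapse = ", "), "\n")
  invisible(x)
}

## sample ids belonging to a group
group_samples <- function(em, group) {
  s <- em$design$sample[em$design$group == group]
  if (length(s) == 0L) stop_validation("no samples in group '", group, "'")
  s
}

groups_of <- function(em) unique(em$design$group)
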