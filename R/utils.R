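# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic stage seeds: one root seed reproducibly derives a distinct
## seed per pipeline stage, so any stage can be re-run in isolation.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 7
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 100000) * 7919 + h) %% 2147483647L
}

## set.seed() scoped to an expression; restores (or removes) .Random.seed
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("thlineage_validation_error", "error")))
}

assert_probability <- function(x, name, open0 = FALSE, open1 = FALSE) {
  bad <- !is.numeric(x) | is.na(x) | x < 0 | x > 1 |
    (open0 & x == 0) | (open1 & x == 1)
  if (any(bad)) stop_validation(name, " must lie in [0,1]",
                                if (open0 || open1) " (open bound violated)")
  invisible(x)
}

f1_score <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  if (tp == 0) return(0)
  prec <- tp / length(predicted)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
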