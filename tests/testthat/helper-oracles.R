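# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration, never through the package's own
# code paths.

## Benjamini-Hochberg step-up from the definition:
## adj_(i) = min_{j >= i} p_(j) * n / j, clipped at 1 (order statistics).
bh_stepup_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(p[o][i:n] * n / (i:n)))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

## Hypergeometric upper tail P(X >= k) by exact combinatorial enumeration.
hyper_upper_enum <- function(k, K, N, n) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Quadratic brute-force count of marks overlapping >=1 window (dedup).
overlap_count_bruteforce <- function(win_df, mark_df) {
  hit <- logical(nrow(mark_df))
  for (m in seq_len(nrow(mark_df))) {
    for (w in seq_len(nrow(win_df))) {
      if (mark_df$chrom[m] == win_df$chrom[w] &&
          mark_df$start[m] <= win_df$end[w] &&
          mark_df$end[m] >= win_df$start[w]) {
        hit[m] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

## Small, fast synthetic configuration for unit tests.
small_synthetic_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_genes = 400, n_lncrnas = 40, n_th1_genes = 25,
         n_th2_genes = 25, n_th1_lncrnas = 8, n_th2_lncrnas = 8,
         module_size = 10, n_background_snps = 300, snps_per_trait = 15,
         n_background_marks = c(enhancer = 1500, promoter = 800),
         genome_length = 400 * 50000, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

## Hand-built ExpressionMatrix: values matrix + implied 4-group design.
toy_expression_matrix <- function(values, platform = "toy",
                                  kind = "intensity",
                                  groups = c("Thp", "Th0", "Th1", "Th2")) {
  reps <- ncol(values) / length(groups)
  design <- data.frame(
    sample = colnames(values),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), times = length(groups)),
    stringsAsFactors = FALSE)
  expression_matrix(values, design, platform, kind)
}

## Minimal DE table row(s) for consensus/classification tests.
toy_de_table <- function(feature_id, comparison, log2fc, is_de, platform) {
  data.frame(feature_id = feature_id, comparison = comparison,
             log2fc = log2fc, pvalue = 0.001, adj_pvalue = 0.001,
             is_de = is_de, platform = platform, stringsAsFactors = FALSE)
}

## 3-term chain DAG: B -> A -> root.
chain_dag <- function() {
  build_go_dag(data.frame(child = c("A", "B"), parent = c("root", "A"),
                          stringsAsFactors = FALSE))
}

## Construct a vector with an exact target correlation to x (up to fp error).
vector_with_cor <- function(x, r, z = NULL) {
  xs <- scale(x)[, 1]
  if (is.null(z)) z <- seq_along(x)^2
  zr <- stats::residuals(stats::lm(z ~ xs))
  zs <- zr / sqrt(sum(zr^2) / (length(x) - 1))
  r * xs + sqrt(1 - r^2) * zs
}
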