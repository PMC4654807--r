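# Size factors, variance stabilization, moderated t, BH, DE filter.

test_that("median-of-ratios size factors: identity, hand case, equivariance", {
  c1 <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(median_of_ratios_size_factors(c1)), c(1, 1))

  ## rows (100, 200) and (300, 600): geometric means 141.42 / 424.26, both
  ## samples' ratios are sqrt(1/2) and sqrt(2); geometric mean already 1
  c2 <- matrix(c(100, 300, 200, 600), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  sf <- median_of_ratios_size_factors(c2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)

  ## scaling one sample by 3 multiplies its factor by 3 relative to others
  set.seed(1)
  m <- matrix(rnbinom(300, mu = 100, size = 10) + 1, 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  sf0 <- median_of_ratios_size_factors(m)
  m2 <- m; m2[, 3] <- m[, 3] * 3
  sf1 <- median_of_ratios_size_factors(m2)
  expect_equal(unname((sf1[3] / sf1[1]) / (sf0[3] / sf0[1])), 3,
               tolerance = 1e-9)
  ## permutation of gene rows leaves factors unchanged
  expect_equal(median_of_ratios_size_factors(m[sample(50), ]), sf0)
  ## error path: no gene positive everywhere
  z <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(median_of_ratios_size_factors(z), "no gene")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(600, mu = 50, size = 5) + 1, 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  sf <- median_of_ratios_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))        # same geometric-mean-1 convention
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("variance stabilization: anchors and monotonicity", {
  m <- matrix(c(0, 2, 7, 13), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  v <- variance_stabilize(m, size_factors = c(a = 2, b = 1))
  expect_equal(v["g1", "a"], 0)            # zero count -> 0
  expect_equal(v["g2", "a"], log2(2))      # count == factor -> 1
  set.seed(3)
  r <- matrix(rpois(200, 20), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  vr <- variance_stabilize(r)
  for (j in 1:4) {
    o <- order(r[, j])
    expect_true(all(diff(vr[o, j]) >= 0))  # monotone in counts per sample
  }
})

test_that("moderated t reduces to the ordinary t-test when d0 = 0", {
  set.seed(4)
  vals <- matrix(rnorm(40 * 6, 8), 40, 6,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  em <- toy_expression_matrix(vals, groups = c("Thp", "Th1"))
  tab <- moderated_t_test(em, "Thp", "Th1", d0 = 0)
  for (g in sample(rownames(vals), 5)) {
    tt <- t.test(vals[g, 4:6], vals[g, 1:3], var.equal = TRUE)
    expect_equal(tab$pvalue[tab$feature_id == g], tt$p.value,
                 tolerance = 1e-10)
    expect_equal(tab$t[tab$feature_id == g], unname(tt$statistic),
                 tolerance = 1e-10)
  }
})

test_that("moderated t with d0 = Inf uses the common variance for all genes", {
  set.seed(5)
  vals <- matrix(rnorm(40 * 6, 8), 40, 6,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  em <- toy_expression_matrix(vals, groups = c("Thp", "Th1"))
  tab <- moderated_t_test(em, "Thp", "Th1", d0 = Inf, s02 = 2)
  lfc <- rowMeans(vals[, 4:6]) - rowMeans(vals[, 1:3])
  expect_equal(tab$t, unname(lfc / sqrt(2 * (2 / 3))), tolerance = 1e-10)
})

test_that("variance prior recovered by moment matching", {
  ## sigma2_g ~ scaled-inv-chi2(d0 = 4, s02 = 2); s2 | sigma2 ~ sigma2*chi2_df/df
  d0 <- 4; s02 <- 2; df <- 4; n_genes <- 5000
  for (seed in 1:10) {
    set.seed(seed)
    sigma2 <- d0 * s02 / rchisq(n_genes, d0)
    s2 <- sigma2 * rchisq(n_genes, df) / df
    fit <- thlineage:::fit_variance_prior(s2, df)
    expect_lt(abs(fit$s02 - s02) / s02, 0.10)
    expect_lt(abs(fit$d0 - d0) / d0, 0.25)
  }
})

test_that("moderated t agrees with the limma reference on shared data", {
  skip_if_not_installed("limma")
  set.seed(6)
  vals <- matrix(rnorm(500 * 6, 8, 1), 500, 6,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  vals[1:50, 4:6] <- vals[1:50, 4:6] + 2
  em <- toy_expression_matrix(vals, groups = c("Thp", "Th1"))
  tab <- moderated_t_test(em, "Thp", "Th1")
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(tab$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  ## hyperparameters and p-values come from the same model family; they agree
  ## closely though the estimators differ in finite-sample details
  expect_equal(cor(log(tab$pvalue), log(fit$p.value[, 2])), 1,
               tolerance = 1e-3)
  expect_lt(max(abs(tab$pvalue - fit$p.value[, 2])), 0.01)
})

test_that("count DE test: null p-values uniform, planted effects powered", {
  set.seed(7)
  counts <- matrix(rnbinom(2000 * 6, mu = 256, size = 20), 2000, 6,
                   dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  em <- toy_expression_matrix(counts, kind = "count", groups = c("Thp", "Th1"))
  tab <- count_de_test(em, "Thp", "Th1")
  ks <- stats::ks.test(tab$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)

  ## plant a 4-fold change in 500 genes
  counts2 <- counts
  counts2[1:500, 4:6] <- matrix(
    rnbinom(500 * 3, mu = 256 * 4, size = 20), 500, 3)
  em2 <- toy_expression_matrix(counts2, kind = "count",
                               groups = c("Thp", "Th1"))
  tab2 <- apply_de_filter(count_de_test(em2, "Thp", "Th1"))
  power <- mean(tab2$is_de[1:500])
  expect_gte(power, 0.9)
  ## false positives controlled among the 1500 nulls
  expect_lt(mean(tab2$is_de[501:2000]), 0.01)
})

test_that("doubling all counts leaves the stabilized log2FC invariant", {
  set.seed(8)
  counts <- matrix(rnbinom(200 * 6, mu = 300, size = 20) + 50, 200, 6,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  em <- toy_expression_matrix(counts, kind = "count", groups = c("Thp", "Th1"))
  em2 <- toy_expression_matrix(counts * 2, kind = "count",
                               groups = c("Thp", "Th1"))
  t1 <- count_de_test(em, "Thp", "Th1")
  t2 <- count_de_test(em2, "Thp", "Th1")
  expect_equal(t1$log2fc, t2$log2fc, tolerance = 0.02)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)                # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # symmetry
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_stepup_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("DE filter applies strict thresholds and presence refinement", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    comparison = "Thp_vs_Th1",
                    log2fc = c(1.01, 1.0, 3, -1.5),
                    pvalue = c(0.049, 0.001, 0.001, 0.001),
                    adj_pvalue = NA_real_, is_de = NA, platform = "x",
                    stringsAsFactors = FALSE)
  ## BH keeps the largest p at 0.049 (< 0.05) here
  presence <- matrix(c(TRUE, TRUE, FALSE, TRUE,    # Thp
                       TRUE, TRUE, FALSE, TRUE),   # Th1
                     4, 2, dimnames = list(c("a", "b", "c", "d"),
                                           c("Thp", "Th1")))
  out <- apply_de_filter(tab, presence)
  expect_true(out$is_de[out$feature_id == "a"])    # 0.049 / 1.01: DE
  expect_false(out$is_de[out$feature_id == "b"])   # log2fc exactly 1: not DE
  expect_false(out$is_de[out$feature_id == "c"])   # absent in both groups
  expect_true(out$is_de[out$feature_id == "d"])    # down-regulation counts
  ## idempotence
  expect_identical(apply_de_filter(out, presence), out)
  ## refinement rule is switchable
  out2 <- apply_de_filter(tab, presence, refine = "none")
  expect_true(out2$is_de[out2$feature_id == "c"])
})
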