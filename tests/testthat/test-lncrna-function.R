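# GO enrichment (classic/elim), co-expression network, attribution, trend.

test_that("classic Fisher enrichment equals exact enumeration", {
  ## worked case: universe 20, term annotates 5, study of 5 overlaps 4:
  ## p = [C(5,4)C(15,1) + C(5,5)C(15,0)] / C(20,5) = 76/15504
  dag <- build_go_dag(data.frame(child = "T1", parent = "root"))
  genes <- paste0("g", 1:20)
  ann <- data.frame(gene_id = genes[1:5], term_id = "T1")
  study <- genes[c(1:4, 10)]
  res <- go_enrichment(study, genes, ann, dag, algorithm = "classic")
  expect_equal(res$pvalue[res$term_id == "T1"], 76 / 15504,
               tolerance = 1e-12)
  expect_equal(res$pvalue[res$term_id == "T1"],
               hyper_upper_enum(4, 5, 20, 5), tolerance = 1e-14)
  ## random small tables against the enumeration oracle
  set.seed(31)
  for (i in 1:50) {
    N <- sample(5:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("u", 1:N)
    ann_i <- data.frame(gene_id = uni[1:K], term_id = "T1")
    study_i <- sample(uni, n)
    r <- go_enrichment(study_i, uni, ann_i, dag, algorithm = "classic",
                       min_term_size = 1)
    k <- length(intersect(study_i, uni[1:K]))
    expect_equal(r$pvalue[r$term_id == "T1"], hyper_upper_enum(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("elim removes significant children's genes from ancestors", {
  ## chain root <- A <- B; B significant, so A is re-tested without B's genes
  dag <- chain_dag()
  genes <- paste0("g", 1:20)
  ann <- rbind(data.frame(gene_id = genes[1:6], term_id = "B"),
               data.frame(gene_id = genes[7:10], term_id = "A"),
               data.frame(gene_id = genes, term_id = "root"))
  study <- c(genes[1:4], genes[7])   # 4 of B's genes, 1 of A's own
  classic <- go_enrichment(study, genes, ann, dag, algorithm = "classic")
  elim <- go_enrichment(study, genes, ann, dag, algorithm = "elim",
                        alpha_elim = 0.05)
  pB <- hyper_upper_enum(4, 6, 20, 5)
  expect_equal(classic$pvalue[classic$term_id == "B"], pB, tolerance = 1e-12)
  expect_lt(pB, 0.05)                                  # B is eliminated
  ## classic A: K = 10 (6 inherited + 4 own), k = 5
  expect_equal(classic$pvalue[classic$term_id == "A"],
               hyper_upper_enum(5, 10, 20, 5), tolerance = 1e-12)
  ## elim A: hand-built table after removing B's genes: K = 4, k = 1
  expect_equal(elim$pvalue[elim$term_id == "A"],
               hyper_upper_enum(1, 4, 20, 5), tolerance = 1e-12)
  expect_equal(elim$pvalue[elim$term_id == "B"], pB, tolerance = 1e-12)

  ## with no significant children, elim reproduces classic exactly
  elim0 <- go_enrichment(study, genes, ann, dag, algorithm = "elim",
                         alpha_elim = 1e-12)
  classic_o <- classic[order(classic$term_id), ]
  elim0_o <- elim0[order(elim0$term_id), ]
  expect_equal(classic_o$pvalue, elim0_o$pvalue, tolerance = 1e-14)
})

test_that("true-path propagation makes term sets supersets of children", {
  dag <- chain_dag()
  ann <- data.frame(gene_id = c("x", "y", "z"), term_id = c("B", "A", "B"))
  t2g <- propagate_annotations(ann, dag)
  expect_setequal(t2g$B, c("x", "z"))
  expect_setequal(t2g$A, c("x", "y", "z"))
  expect_setequal(t2g$root, c("x", "y", "z"))
  expect_error(build_go_dag(data.frame(child = c("A", "B", "root"),
                                       parent = c("root", "A", "B"))),
               "root|cycle")
})

test_that("co-expression edges require |r| strictly above the threshold", {
  set.seed(32)
  base <- rnorm(8, 8, 2)
  samples <- paste0("s", 1:8)
  lnc <- rbind(L1 = base)
  colnames(lnc) <- samples
  gene <- rbind(gA = 2 * base + 3,                        # exact affine: r = 1
                gB = -base + 20,                          # negated: r = -1
                gC = vector_with_cor(base, 0.900001),     # just above
                gD = vector_with_cor(base, 0.899999),     # just below
                gE = rnorm(8))
  colnames(gene) <- samples
  edges <- coexpression_network(lnc, gene, threshold = 0.9)
  key <- paste(edges$lncrna_id, edges$gene_id)
  expect_true("L1 gA" %in% key)
  expect_true("L1 gB" %in% key)          # absolute correlation
  expect_equal(edges$r[edges$gene_id == "gB"], -1, tolerance = 1e-12)
  expect_true("L1 gC" %in% key)
  expect_false("L1 gD" %in% key)         # strict threshold
  ## hand-computed correlation on a 4-sample profile
  x <- c(1, 3, 4, 9); y <- c(2, 5, 5, 13)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  l4 <- rbind(L = x); g4 <- rbind(G = y)
  colnames(l4) <- colnames(g4) <- paste0("t", 1:4)
  e4 <- coexpression_network(l4, g4, threshold = 0)
  expect_equal(e4$r, r_hand, tolerance = 1e-12)
  ## constant features are excluded with a warning
  lnc_const <- rbind(L1 = rep(5, 8))
  colnames(lnc_const) <- samples
  expect_warning(
    e_const <- coexpression_network(lnc_const, gene, threshold = 0.9),
    "constant")
  expect_equal(nrow(e_const), 0)
  expect_error(coexpression_network(lnc[, 1:2, drop = FALSE],
                                    gene[, 1:2, drop = FALSE]), "3 shared")
})

test_that("GO terms are attributed through co-expressed genes, strictly", {
  dag <- build_go_dag(data.frame(child = c("T1", "T2"), parent = "root"))
  genes <- paste0("g", 1:30)
  ann <- rbind(data.frame(gene_id = genes[1:6], term_id = "T1"),
               data.frame(gene_id = genes[7:12], term_id = "T2"))
  edges <- data.frame(lncrna_id = "L1", gene_id = genes[1:5], r = 0.95,
                      n_samples = 12)
  attr1 <- attribute_terms_to_lncrnas(edges, ann, dag, genes,
                                      algorithm = "classic")
  expect_true(any(attr1$lncrna_id == "L1" & attr1$term_id == "T1"))
  expect_false(any(attr1$term_id == "T2"))
  ## no edges -> no attribution
  no_edges <- edges[0, ]
  expect_equal(nrow(attribute_terms_to_lncrnas(no_edges, ann, dag, genes)), 0)
  ## strict cutoff: a term exactly at the cutoff is not attributed
  p_t1 <- attr1$pvalue[attr1$term_id == "T1"][1]
  at_cut <- attribute_terms_to_lncrnas(edges, ann, dag, genes,
                                       algorithm = "classic", cutoff = p_t1)
  expect_false(any(at_cut$term_id == "T1"))
})

test_that("biotype tally handles single-category and unknown biotypes", {
  ann <- genomic_features(data.frame(
    id = c("l1", "l2", "l3"), chrom = "chr1",
    start = c(1, 100, 200), end = c(50, 150, 250), strand = "+",
    biotype = c("antisense", "antisense", "weird_type"), type = "lncRNA"))
  t1 <- classify_biotype(c("l1", "l2"), ann)
  expect_equal(t1, data.frame(biotype = "antisense", n = 2L))
  t2 <- classify_biotype(c("l1", "l3"), ann)
  expect_equal(t2$n[t2$biotype == "other"], 1L)
  expect_equal(nrow(classify_biotype(character(0), ann)), 0)
})

test_that("pair correlation trend summarizes vicinity pairs", {
  samples <- paste0("s", 1:6)
  e <- rbind(L1 = 1:6, G1 = 1:6, G2 = c(3, 1, 4, 1, 5, 9))
  colnames(e) <- samples
  pairs <- data.frame(lncrna_id = c("L1", "L1"), gene_id = c("G1", "G2"))
  tr <- pair_correlation_trend(pairs, e, e)
  expect_equal(tr$pairs$r[1], 1)          # identical profiles
  expect_equal(tr$n_pairs, 2)
  ## empty pair list: no error, NA summaries
  tr0 <- pair_correlation_trend(pairs[0, ], e, e)
  expect_equal(tr0$n_pairs, 0)
  expect_true(is.na(tr0$mean_r))
})

test_that("planted vicinity pairs show a positive expression trend", {
  cfg <- small_synthetic_config(seed = 33)
  data <- generate_synthetic_dataset(cfg)
  vst <- variance_stabilize(data$matrices$rnaseq$values)
  tr <- pair_correlation_trend(data$truth$vicinity_pairs, vst, vst)
  expect_gt(tr$mean_r, 0)
  expect_gt(tr$fraction_positive, 0.8)
})
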