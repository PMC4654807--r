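# Synthetic-data generator: determinism, planted structure, file round trips.

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- small_synthetic_config(seed = 21)
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(cfg)
  expect_identical(d1$matrices$affy$values, d2$matrices$affy$values)
  expect_identical(d1$matrices$rnaseq$values, d2$matrices$rnaseq$values)
  expect_identical(d1$detection_p, d2$detection_p)
  expect_identical(as.data.frame(d1$annotation), as.data.frame(d2$annotation))
  expect_identical(d1$snps, d2$snps)
  expect_identical(as.data.frame(d1$marks$enhancers$Th1),
                   as.data.frame(d2$marks$enhancers$Th1))
  expect_identical(d1$go$gene2term, d2$go$gene2term)
  expect_identical(d1$truth[names(d1$truth) != "expressed_features"],
                   d2$truth[names(d2$truth) != "expressed_features"])
})

test_that("zero effect size plants nothing but keeps expression structure", {
  cfg <- small_synthetic_config(seed = 22, effect_lfc = 0)
  out <- generate_expression(cfg)
  expect_length(out$truth$th1_genes, 0)
  expect_length(out$truth$th2_genes, 0)
  expect_length(out$truth$th1_lncrnas, 0)
  expect_equal(nrow(out$truth$vicinity_pairs), 0)
  expect_gt(length(out$truth$expressed_features$Thp), 0)
})

test_that("planted fold changes match the generating effect size", {
  cfg <- synthetic_config(seed = 23)      # default: 10,000 genes, lfc 2
  out <- generate_expression(cfg)
  em <- out$matrices$affy
  th1 <- out$truth$th1_genes
  idx_th1 <- em$design$sample[em$design$group == "Th1"]
  idx_thp <- em$design$sample[em$design$group == "Thp"]
  lfc <- rowMeans(em$values[th1, idx_th1]) - rowMeans(em$values[th1, idx_thp])
  signed <- lfc * out$truth$effect_sign[th1]   # align planted directions
  expect_lt(abs(mean(signed) - cfg$effect_lfc), 0.1)
  ## effect signs are identical across platforms
  em2 <- out$matrices$rnaseq
  v <- variance_stabilize(em2$values)
  lfc2 <- rowMeans(v[th1, paste0("rnaseq_Th1_", 1:3)]) -
    rowMeans(v[th1, paste0("rnaseq_Thp_", 1:3)])
  expect_gt(cor(sign(lfc), sign(lfc2)), 0.95)
  ## no shift in the Th0 activation control
  lfc0 <- rowMeans(em$values[th1, em$design$sample[em$design$group == "Th0"]]) -
    rowMeans(em$values[th1, idx_thp])
  expect_lt(abs(mean(lfc0)), 0.1)
})

test_that("annotation round-trips through GTF and satisfies the vicinity rule", {
  cfg <- small_synthetic_config(seed = 24)
  ann <- generate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, path)
  back <- read_annotation_gtf(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(ann)))
  expect_equal(back$id, ann$id)
  expect_equal(back$biotype, ann$biotype)
  ## every planted vicinity pair is recovered by the vicinity operation
  truth <- generate_expression(cfg)$truth
  vp <- truth$vicinity_pairs
  geo <- lncrna_gene_vicinity(ann[match(unique(vp$lncrna_id), ann$id)],
                              ann[match(unique(vp$gene_id), ann$id)])
  expect_true(all(paste(vp$lncrna_id, vp$gene_id) %in%
                    paste(geo$lncrna_id, geo$gene_id)))
  ## gene bodies do not overlap
  genes <- ann[ann$type == "gene"]
  expect_equal(sum(GenomicRanges::countOverlaps(genes, genes)),
               length(genes))
  ## no lncRNA with its own identifier appears twice
  expect_false(any(duplicated(ann$id)))
  ## placement failure is reported
  expect_error(generate_annotation(small_synthetic_config(
    genome_length = 1e6)), "too small")
})

test_that("lncRNA biotype tally matches the configured proportions exactly", {
  cfg <- small_synthetic_config(seed = 25)
  ann <- generate_annotation(cfg)
  lnc <- ann$id[ann$type == "lncRNA"]
  tally <- classify_biotype(lnc, ann)
  props <- cfg$lncrna_biotype_props / sum(cfg$lncrna_biotype_props)
  raw <- props * cfg$n_lncrnas
  cnt <- floor(raw)
  rem <- cfg$n_lncrnas - sum(cnt)
  cnt[order(raw - cnt, decreasing = TRUE)[seq_len(rem)]] <-
    cnt[order(raw - cnt, decreasing = TRUE)[seq_len(rem)]] + 1
  for (b in names(cnt)[cnt > 0])
    expect_equal(tally$n[tally$biotype == b], unname(cnt[b]))
})

test_that("marks: enriched near planted genes, uniform under factor 1", {
  cfg <- small_synthetic_config(seed = 26)
  truth <- generate_expression(cfg)$truth
  ann <- generate_annotation(cfg)
  marks <- generate_marks(cfg, ann, truth)
  ## BED round trip preserves intervals
  path <- withr::local_tempfile(fileext = ".bed")
  write_marks_bed(marks$promoters$Th1, path)
  back <- read_marks_bed(path)
  expect_equal(GenomicRanges::start(back),
               GenomicRanges::start(marks$promoters$Th1))
  expect_equal(GenomicRanges::end(back),
               GenomicRanges::end(marks$promoters$Th1))
  expect_true(all(back$lineage == "Th1"))

  ## factor 5: promoter-window counts exceed the uniform Poisson expectation
  genes <- ann[match(truth$th1_genes, ann$id)]
  obs <- count_marks_near_set(genes, marks$promoters$Th1,
                              cfg$promoter_window, cfg$promoter_window)
  win <- GenomicRanges::reduce(feature_window(
    genes, cfg$promoter_window, cfg$promoter_window, "tss",
    strand_aware = FALSE), ignore.strand = TRUE)
  lambda <- cfg$n_background_marks[["promoter"]] / cfg$genome_length *
    sum(GenomicRanges::width(win))
  expect_gt(obs, qpois(0.999, lambda))

  ## factor 1: counts consistent with the uniform background
  cfg1 <- small_synthetic_config(seed = 26, mark_enrichment_factor = 1)
  marks1 <- generate_marks(cfg1, ann, truth)
  obs1 <- count_marks_near_set(genes, marks1$promoters$Th1,
                               cfg$promoter_window, cfg$promoter_window)
  expect_gt(poisson.test(obs1, lambda)$p.value, 0.01)
})

test_that("SNPs: planted clusters within 100 kb, background fraction correct", {
  cfg <- small_synthetic_config(seed = 27)
  truth <- generate_expression(cfg)$truth
  ann <- generate_annotation(cfg)
  out <- generate_snps(cfg, ann, truth)
  expect_true(all(out$snps$pvalue > 0 & out$snps$pvalue <= 1))
  ## every planted cluster gene is recovered by associate_genes at 100 kb
  kept <- filter_snps(out$snps)
  assoc <- associate_genes(kept, ann[ann$type == "gene"], window = 100000)
  for (tr in names(out$trait_gene_map)) {
    hit <- assoc$gene_id[assoc$trait == tr]
    expect_true(all(out$trait_gene_map[[tr]] %in% hit))
  }
  ## background significant fraction within binomial error
  bg <- out$snps[!out$snps$trait %in% names(out$trait_gene_map), ]
  phat <- mean(bg$pvalue <= 1e-5)
  se <- sqrt(cfg$snp_sig_fraction * (1 - cfg$snp_sig_fraction) / nrow(bg))
  expect_lt(abs(phat - cfg$snp_sig_fraction), 4 * se)
  ## p-values span both sides of the filter threshold
  expect_gt(sum(bg$pvalue > 1e-5), 0)
  expect_gt(sum(bg$pvalue <= 1e-5), 0)
})

test_that("generated GO DAG is acyclic with true-path annotations", {
  cfg <- small_synthetic_config(seed = 28)
  ann <- generate_annotation(cfg)
  go <- generate_go(cfg, ann)
  dag <- go$dag
  ## topological order exists (acyclic) and ends at the root
  expect_equal(dag$topo_order[length(dag$topo_order)], dag$root)
  t2g <- split(go$gene2term$gene_id, go$gene2term$term_id)
  ## every annotated gene reaches the root
  expect_setequal(unique(go$gene2term$gene_id), t2g[[dag$root]])
  ## term gene sets are monotone from child to parent
  for (t in dag$terms) {
    for (p in dag$parents[[t]]) {
      expect_true(all(t2g[[t]] %in% t2g[[p]]))
    }
  }
  ## the module term annotates exactly the planted module genes
  truth <- generate_expression(cfg)$truth
  expect_setequal(t2g[[go$module_term]], truth$module$genes)
})
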