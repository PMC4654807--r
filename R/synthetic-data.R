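## Synthetic multi-platform dataset with planted ground truth.
##
## Emulates the study design the pipeline targets: 4 T-helper subtypes
## (Thp naive precursor, Th0 activation control, Th1, Th2) with replicates,
## profiled on three platforms (two intensity/array-like, one count/
## sequencing-like). Log2 expression is bimodal (unexpressed vs expressed
## component); lineage-specific genes and lncRNAs are planted with
## sign-consistent log2 fold-changes applied only in the matching polarized
## subtype; lncRNAs are placed in or out of the 5 kb-up/30 kb-down vicinity
## of genes; enhancer/promoter marks are densified near planted genes; SNPs
## of selected traits cluster near planted genes; and a small GO DAG carries
## a term annotating a co-expressed gene module tied to one lncRNA.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the demonstration conditions used throughout the test suite:
#' 10,000 genes (300 planted Th1- plus 300 Th2-specific), 200 lncRNAs
#' (30 + 30 planted, half of them placed in vicinity of a same-lineage gene),
#' a log2 effect of 2, 3 replicates per subtype on 3 platforms, and a
#' bimodal log2-intensity structure with components N(5, 1) and N(11, 1.5).
#'
#' @param n_genes,n_lncrnas feature counts.
#' @param n_th1_genes,n_th2_genes,n_th1_lncrnas,n_th2_lncrnas planted
#'   lineage-specific feature counts.
#' @param vicinity_fraction fraction of planted lineage lncRNAs placed within
#'   the 5 kb-up/30 kb-down vicinity of a same-lineage planted gene.
#' @param effect_lfc magnitude of the planted log2 fold-change (0 plants
#'   nothing).
#' @param replicates_per_group replicates per subtype.
#' @param platforms named character vector of platform kinds
#'   (`"intensity"` or `"count"`).
#' @param detection_platform intensity platform for which an
#'   Illumina-style detection p-value matrix is generated (NULL for none).
#' @param expressed_fraction prior probability that a feature is expressed.
#' @param mixture_means,mixture_sds log2-scale parameters of the unexpressed
#'   (first) and expressed (second) components.
#' @param replicate_sd replicate noise sd on the log2 scale.
#' @param nb_dispersion negative-binomial dispersion of the count platform
#'   (`size = 1/dispersion`).
#' @param genome_length,n_chromosomes synthetic genome size in bp and number
#'   of chromosomes.
#' @param gene_length_range,lncrna_length feature lengths in bp.
#' @param lncrna_biotype_props named biotype proportions for lncRNAs.
#' @param n_background_marks,mark_length per mark class (enhancer, promoter).
#' @param mark_enrichment_factor density multiplier of matching-lineage marks
#'   inside windows around planted lineage genes.
#' @param enhancer_window,promoter_window TSS window half-widths in bp.
#' @param n_background_snps,snp_sig_fraction background SNP count and the
#'   fraction with association p <= 1e-5.
#' @param snp_cluster_traits named character vector: trait name -> lineage
#'   (`"Th1"`/`"Th2"`) whose planted genes attract that trait's SNPs.
#' @param snps_per_trait SNPs planted per cluster trait.
#' @param module_size,module_latent_sd size of the planted co-expression
#'   gene module attached to one lncRNA, and the sd of their shared
#'   per-sample latent signal (count platform).
#' @param n_go_mid,n_go_leaves_per_mid,go_term_size GO DAG shape and the
#'   annotation size of non-module leaf terms.
#' @param seed RNG seed; all generators derive stage seeds from it.
#' @return validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 10000, n_lncrnas = 200,
                             n_th1_genes = 300, n_th2_genes = 300,
                             n_th1_lncrnas = 30, n_th2_lncrnas = 30,
                             vicinity_fraction = 0.5,
                             effect_lfc = 2, replicates_per_group = 3,
                             platforms = c(affy = "intensity",
                                           illumina = "intensity",
                                           rnaseq = "count"),
                             detection_platform = "illumina",
                             expressed_fraction = 0.5,
                             mixture_means = c(5, 11),
                             mixture_sds = c(1, 1.5),
                             replicate_sd = 0.25,
                             nb_dispersion = 0.05,
                             genome_length = 5e8, n_chromosomes = 1,
                             gene_length_range = c(1000, 3000),
                             lncrna_length = 500,
                             lncrna_biotype_props = c(
                               antisense = 0.48, lincRNA = 0.26,
                               processed_transcript = 0.20,
                               sense_intronic = 0.04,
                               sense_overlapping = 0.015,
                               `3prime_overlapping_ncRNA` = 0.005),
                             n_background_marks = c(enhancer = 2000,
                                                    promoter = 1000),
                             mark_length = c(enhancer = 1000, promoter = 500),
                             mark_enrichment_factor = 5,
                             enhancer_window = 125000, promoter_window = 2500,
                             n_background_snps = 2000,
                             snp_sig_fraction = 0.25,
                             snp_cluster_traits = c(`planted trait` = "Th1"),
                             snps_per_trait = 60,
                             module_size = 15, module_latent_sd = 1.5,
                             n_go_mid = 5, n_go_leaves_per_mid = 3,
                             go_term_size = 20,
                             seed = 1) {
  cfg <- structure(as.list(environment()), class = "SyntheticConfig")
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param config a `SyntheticConfig`.
#' @export
validate_synthetic_config <- function(config) {
  with(config, {
    if (n_th1_genes + n_th2_genes + module_size > n_genes)
      stop_validation("planted gene sets exceed n_genes")
    if (n_th1_lncrnas + n_th2_lncrnas + 1 > n_lncrnas)
      stop_validation("planted lncRNA sets exceed n_lncrnas")
    assert_probability(expressed_fraction, "expressed_fraction",
                       open0 = TRUE, open1 = TRUE)
    assert_probability(vicinity_fraction, "vicinity_fraction")
    if (effect_lfc < 0) stop_validation("effect_lfc must be >= 0")
    if (replicates_per_group < 1) stop_validation("need >= 1 replicate")
    if (mixture_means[1] >= mixture_means[2])
      stop_validation("mixture_means must be increasing (unexpressed < expressed)")
    if (any(mixture_sds <= 0) || replicate_sd < 0 || nb_dispersion <= 0)
      stop_validation("scale parameters must be positive")
    if (!all(platforms %in% c("intensity", "count")))
      stop_validation("platform kinds must be 'intensity' or 'count'")
  })
  config
}

## Deterministic identifier layout shared by all generators: which ids are
## planted where depends only on the config, never on the RNG, so every
## generator can reconstruct it independently.
planted_sets <- function(config) {
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrnas))
  n1 <- config$n_th1_genes; n2 <- config$n_th2_genes
  l1 <- config$n_th1_lncrnas; l2 <- config$n_th2_lncrnas
  planted <- config$effect_lfc > 0
  th1_genes <- if (planted) gene_ids[seq_len(n1)] else character(0)
  th2_genes <- if (planted) gene_ids[n1 + seq_len(n2)] else character(0)
  module_genes <- gene_ids[n1 + n2 + seq_len(config$module_size)]
  th1_lncrnas <- if (planted) lnc_ids[seq_len(l1)] else character(0)
  th2_lncrnas <- if (planted) lnc_ids[l1 + seq_len(l2)] else character(0)
  module_lncrna <- lnc_ids[config$n_lncrnas]
  nv1 <- floor(config$vicinity_fraction * length(th1_lncrnas))
  nv2 <- floor(config$vicinity_fraction * length(th2_lncrnas))
  vicinity_pairs <- rbind(
    if (nv1 > 0) data.frame(lncrna_id = th1_lncrnas[seq_len(nv1)],
                            gene_id = th1_genes[seq_len(nv1)],
                            lineage = "Th1", stringsAsFactors = FALSE),
    if (nv2 > 0) data.frame(lncrna_id = th2_lncrnas[seq_len(nv2)],
                            gene_id = th2_genes[seq_len(nv2)],
                            lineage = "Th2", stringsAsFactors = FALSE))
  if (is.null(vicinity_pairs))
    vicinity_pairs <- data.frame(lncrna_id = character(0),
                                 gene_id = character(0),
                                 lineage = character(0),
                                 stringsAsFactors = FALSE)
  list(gene_ids = gene_ids, lnc_ids = lnc_ids,
       th1_genes = th1_genes, th2_genes = th2_genes,
       th1_lncrnas = th1_lncrnas, th2_lncrnas = th2_lncrnas,
       module_genes = module_genes, module_lncrna = module_lncrna,
       vicinity_pairs = vicinity_pairs)
}

#' Generate multi-platform expression matrices with ground truth
#'
#' Each feature is unexpressed or expressed (drawn from the low/high mixture
#' component, per platform); planted Th1-specific features are shifted by
#' +-`effect_lfc` in Th1 samples only (relative to Thp and Th0), analogously
#' Th2, with the effect sign identical across platforms. Intensity platforms
#' add Gaussian replicate noise; the count platform draws negative-binomial
#' counts with mean `2^signal`. Intensity platforms carry genes only; the
#' count platform carries genes and lncRNAs. A planted co-expression module
#' (one lncRNA plus `module_size` genes) shares a per-sample latent signal
#' on the count platform.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrices` (named list of [expression_matrix()]),
#'   `detection_p` (matrix or NULL), and `truth` (a `GroundTruth` list:
#'   planted lineage sets, per-group expressed features, effect signs,
#'   vicinity pairs, module composition).
#' @export
generate_expression <- function(config) {
  config <- validate_synthetic_config(config)
  ps <- planted_sets(config)
  groups <- c("Thp", "Th0", "Th1", "Th2")
  reps <- config$replicates_per_group
  feat_all <- c(ps$gene_ids, ps$lnc_ids)
  n_all <- length(feat_all)

  with_seed(derive_seed(config$seed, "expression"), {
    expressed <- stats::runif(n_all) < config$expressed_fraction
    names(expressed) <- feat_all
    forced <- c(ps$th1_genes, ps$th2_genes, ps$module_genes,
                ps$th1_lncrnas, ps$th2_lncrnas, ps$module_lncrna)
    expressed[forced] <- TRUE

    planted <- c(ps$th1_genes, ps$th2_genes, ps$th1_lncrnas, ps$th2_lncrnas)
    sign_of <- stats::setNames(sample(c(-1, 1), length(planted), replace = TRUE),
                               planted)
    ## vicinity lncRNAs inherit the paired gene's sign (positive coupling)
    vp <- ps$vicinity_pairs
    if (nrow(vp) > 0) sign_of[vp$lncrna_id] <- sign_of[vp$gene_id]
    lineage_of <- stats::setNames(
      rep(c("Th1", "Th2", "Th1", "Th2"),
          c(length(ps$th1_genes), length(ps$th2_genes),
            length(ps$th1_lncrnas), length(ps$th2_lncrnas))), planted)

    sample_groups <- rep(groups, each = reps)
    module <- c(ps$module_genes, ps$module_lncrna)

    matrices <- list()
    for (pf in names(config$platforms)) {
      kind <- config$platforms[[pf]]
      feats <- if (kind == "count") feat_all else ps$gene_ids
      nf <- length(feats)
      ns <- length(sample_groups)
      comp <- expressed[feats] + 1L
      baseline <- stats::rnorm(nf, config$mixture_means[comp],
                               config$mixture_sds[comp])
      signal <- matrix(baseline, nf, ns)
      for (f in intersect(planted, feats)) {
        i <- match(f, feats)
        hit <- sample_groups == lineage_of[[f]]
        signal[i, hit] <- signal[i, hit] + sign_of[[f]] * config$effect_lfc
      }
      if (kind == "count") {
        latent <- stats::rnorm(ns, 0, config$module_latent_sd)
        mi <- match(module, feats)
        signal[mi, ] <- signal[mi, ] + rep(latent, each = length(mi))
        values <- matrix(
          stats::rnbinom(nf * ns, mu = 2^signal, size = 1 / config$nb_dispersion),
          nf, ns)
      } else {
        values <- signal + stats::rnorm(nf * ns, 0, config$replicate_sd)
      }
      sample_ids <- paste(pf, sample_groups,
                          rep(seq_len(reps), times = length(groups)), sep = "_")
      dimnames(values) <- list(feats, sample_ids)
      design <- data.frame(sample = sample_ids, group = sample_groups,
                           replicate = rep(seq_len(reps), times = length(groups)),
                           stringsAsFactors = FALSE)
      matrices[[pf]] <- expression_matrix(values, design, pf, kind)
    }

    detection_p <- NULL
    dp <- config$detection_platform
    if (!is.null(dp) && dp %in% names(matrices)) {
      tmpl <- matrices[[dp]]$values
      nf <- nrow(tmpl); ns <- ncol(tmpl)
      is_exp <- expressed[rownames(tmpl)]
      mix <- stats::runif(nf * ns) < 0.01
      p_exp <- ifelse(mix, stats::runif(nf * ns, 0, 0.05),
                      stats::runif(nf * ns, 0, 0.009))
      p_abs <- ifelse(mix, stats::runif(nf * ns, 0.001, 0.02),
                      stats::runif(nf * ns, 0.02, 1))
      detection_p <- matrix(ifelse(rep(is_exp, ns), p_exp, p_abs), nf, ns,
                            dimnames = dimnames(tmpl))
    }

    expressed_ids <- names(expressed)[expressed]
    truth <- structure(list(
      th1_genes = ps$th1_genes, th2_genes = ps$th2_genes,
      th1_lncrnas = ps$th1_lncrnas, th2_lncrnas = ps$th2_lncrnas,
      expressed_features = stats::setNames(
        rep(list(expressed_ids), length(groups)), groups),
      effect_sign = sign_of,
      vicinity_pairs = ps$vicinity_pairs,
      module = list(lncrna = ps$module_lncrna, genes = ps$module_genes,
                    term = "GO:0020001"),
      trait_gene_map = list(), enriched_mark_regions = list()
    ), class = "GroundTruth")

    list(matrices = matrices, detection_p = detection_p, truth = truth)
  })
}

## chromosome layout: n_genes slots of slot_size bp split across chromosomes
genome_layout <- function(config) {
  slot_size <- floor(config$genome_length / config$n_genes)
  slots_per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  chroms <- sprintf("chrS%d", seq_len(config$n_chromosomes))
  list(slot_size = slot_size, slots_per_chrom = slots_per_chrom,
       chroms = chroms,
       seqlengths = stats::setNames(rep(slots_per_chrom * slot_size,
                                        config$n_chromosomes), chroms))
}

#' Generate the gene/lncRNA annotation
#'
#' Places non-overlapping gene bodies on a synthetic genome (one gene per
#' genomic slot, slot order randomized), then places lncRNAs: planted
#' vicinity lncRNAs inside the 5 kb-up/30 kb-down window of their paired
#' lineage gene (respecting the gene's strand), all other lncRNAs in slots
#' whose own and neighboring genes are not lineage-planted, well outside any
#' planted gene's vicinity window. lncRNA biotypes follow the configured
#' proportions exactly (largest-remainder rounding).
#'
#' @param config a [synthetic_config()].
#' @return GRanges with mcols `id`, `biotype`, `type` and seqlengths set.
#' @export
generate_annotation <- function(config) {
  config <- validate_synthetic_config(config)
  ps <- planted_sets(config)
  lay <- genome_layout(config)
  min_slot <- 5000 + config$gene_length_range[2] + 30000 +
    config$lncrna_length + 6000
  if (lay$slot_size < min_slot)
    stop_validation("genome_length too small to place features: need slots of ",
                    min_slot, " bp, have ", lay$slot_size)

  with_seed(derive_seed(config$seed, "annotation"), {
    n <- config$n_genes
    slot <- sample.int(n)                      # gene i sits in slot[i]
    chrom_i <- (slot - 1) %/% lay$slots_per_chrom + 1
    local <- (slot - 1) %% lay$slots_per_chrom
    slot_start <- local * lay$slot_size + 1
    glen <- round(stats::runif(n, config$gene_length_range[1],
                               config$gene_length_range[2]))
    gstart <- slot_start + 5000 + sample.int(1000, n, replace = TRUE)
    gend <- gstart + glen - 1
    gstrand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- data.frame(id = ps$gene_ids, chrom = lay$chroms[chrom_i],
                        start = gstart, end = gend, strand = gstrand,
                        biotype = "protein_coding", type = "gene",
                        stringsAsFactors = FALSE)

    ## lncRNA biotype counts: exact largest-remainder apportionment
    props <- config$lncrna_biotype_props / sum(config$lncrna_biotype_props)
    raw <- props * config$n_lncrnas
    cnt <- floor(raw)
    rem <- config$n_lncrnas - sum(cnt)
    if (rem > 0) {
      up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[up] <- cnt[up] + 1
    }
    biotypes <- sample(rep(names(cnt), cnt))

    lnc <- data.frame(id = ps$lnc_ids, chrom = NA_character_,
                      start = NA_real_, end = NA_real_,
                      strand = sample(c("+", "-"), config$n_lncrnas,
                                      replace = TRUE),
                      biotype = biotypes, type = "lncRNA",
                      stringsAsFactors = FALSE)
    rownames(lnc) <- lnc$id
    llen <- config$lncrna_length

    ## vicinity lncRNAs: inside the paired gene's strand-aware body window
    vp <- ps$vicinity_pairs
    for (i in seq_len(nrow(vp))) {
      gi <- match(vp$gene_id[i], genes$id)
      if (genes$strand[gi] == "+") {
        s <- genes$start[gi] - 4000 - llen     # ends 4001 bp upstream
      } else {
        s <- genes$end[gi] + 4001              # starts 4001 bp "upstream" (-)
      }
      lnc[vp$lncrna_id[i], c("chrom", "start", "end")] <-
        list(genes$chrom[gi], s, s + llen - 1)
    }

    ## remaining lncRNAs: slots with no lineage gene in slot-1..slot+1
    lineage_gene <- genes$id %in% c(ps$th1_genes, ps$th2_genes)
    lineage_slot <- rep(FALSE, n + 2)
    lineage_slot[slot[lineage_gene] + 1] <- TRUE   # padded by 1 each side
    eligible <- which(!(lineage_slot[slot] | lineage_slot[slot + 1] |
                          lineage_slot[slot + 2]))
    rest <- setdiff(ps$lnc_ids, vp$lncrna_id)
    if (length(eligible) < length(rest))
      stop_validation("genome_length too small: not enough non-lineage slots ",
                      "for background lncRNAs")
    host <- sample(eligible, length(rest))
    hs <- slot_start[host] + 40000 + sample.int(500, length(rest), replace = TRUE)
    lnc[rest, "chrom"] <- genes$chrom[host]
    lnc[rest, "start"] <- hs
    lnc[rest, "end"] <- hs + llen - 1

    out <- genomic_features(rbind(genes, lnc))
    GenomeInfoDb::seqlengths(out) <- lay$seqlengths[
      GenomeInfoDb::seqlevels(out)]
    out
  })
}

## draw n positions uniformly inside a reduced GRanges territory
sample_in_regions <- function(regions, n, width) {
  if (n <= 0 || length(regions) == 0)
    return(GenomicRanges::GRanges())
  w <- GenomicRanges::width(regions)
  cum <- cumsum(as.numeric(w))
  off <- stats::runif(n, 0, cum[length(cum)])
  ri <- findInterval(off, c(0, cum[-length(cum)]))
  pos <- GenomicRanges::start(regions)[ri] +
    floor(off - c(0, cum)[ri])
  GenomicRanges::GRanges(GenomicRanges::seqnames(regions)[ri],
                         IRanges::IRanges(pos, pos + width - 1))
}

#' Generate lineage-labelled enhancer and promoter marks
#'
#' Background marks are uniform over the genome; inside the TSS windows
#' around planted genes of the matching lineage the density is multiplied by
#' `mark_enrichment_factor` (extra marks are placed uniformly within those
#' windows). With factor 1 the planted regions are indistinguishable from
#' background.
#'
#' @param config a [synthetic_config()].
#' @param annotation GRanges from [generate_annotation()].
#' @param truth `GroundTruth` from [generate_expression()].
#' @return list with `enhancers` and `promoters` (each a named list of
#'   GRanges per lineage, mcols `lineage`, `mark_class`) and
#'   `enriched_regions` (the planted window territories).
#' @export
generate_marks <- function(config, annotation, truth) {
  config <- validate_synthetic_config(config)
  lay <- genome_layout(config)
  genome_total <- sum(as.numeric(lay$seqlengths))
  classes <- list(enhancer = config$enhancer_window,
                  promoter = config$promoter_window)
  planted_genes <- list(Th1 = truth$th1_genes, Th2 = truth$th2_genes)

  with_seed(derive_seed(config$seed, "marks"), {
    out <- list(enhancers = list(), promoters = list(),
                enriched_regions = list())
    whole <- GenomicRanges::GRanges(
      lay$chroms, IRanges::IRanges(1, lay$seqlengths))
    for (lineage in c("Th1", "Th2")) {
      out$enriched_regions[[lineage]] <- list()
      for (cls in names(classes)) {
        wd <- config$mark_length[[cls]]
        n_bg <- config$n_background_marks[[cls]]
        marks <- sample_in_regions(whole, n_bg, wd)
        genes <- annotation[annotation$id %in% planted_genes[[lineage]]]
        if (length(genes) > 0 && config$mark_enrichment_factor > 1) {
          win <- GenomicRanges::reduce(feature_window(
            genes, classes[[cls]], classes[[cls]], "tss",
            strand_aware = FALSE), ignore.strand = TRUE)
          extra_n <- round((config$mark_enrichment_factor - 1) *
                             n_bg / genome_total *
                             sum(as.numeric(GenomicRanges::width(win))))
          marks <- c(marks, sample_in_regions(win, extra_n, wd))
          out$enriched_regions[[lineage]][[cls]] <- win
        }
        marks <- GenomicRanges::sort(marks, ignore.strand = TRUE)
        marks$lineage <- lineage
        marks$mark_class <- cls
        out[[paste0(cls, "s")]][[lineage]] <- marks
      }
    }
    out
  })
}

#' Generate the disease-SNP table
#'
#' Background SNPs are uniform over the genome with association p-values
#' spanning both sides of 1e-5; for every configured cluster trait,
#' significant SNPs (p <= 1e-5) are placed within +-50 kb of planted genes
#' of the trait's lineage, i.e. well inside the +-100 kb association window.
#'
#' @inheritParams generate_marks
#' @return list with `snps` (data.frame `chrom`, `pos`, `trait`, `pvalue`)
#'   and `trait_gene_map` (trait -> planted associated gene ids).
#' @export
generate_snps <- function(config, annotation, truth) {
  config <- validate_synthetic_config(config)
  lay <- genome_layout(config)
  planted_genes <- list(Th1 = truth$th1_genes, Th2 = truth$th2_genes)

  with_seed(derive_seed(config$seed, "snps"), {
    n_bg <- config$n_background_snps
    chrom <- sample(lay$chroms, n_bg, replace = TRUE)
    pos <- floor(stats::runif(n_bg, 1, lay$seqlengths[chrom]))
    sig <- stats::runif(n_bg) < config$snp_sig_fraction
    pval <- ifelse(sig, 10^-stats::runif(n_bg, 5.1, 12),
                   10^-stats::runif(n_bg, 0.3, 4.9))
    trait <- sample(sprintf("background trait %02d", 1:20), n_bg,
                    replace = TRUE)
    snps <- data.frame(chrom = chrom, pos = pos, trait = trait,
                       pvalue = pval, stringsAsFactors = FALSE)

    trait_gene_map <- list()
    for (tr in names(config$snp_cluster_traits)) {
      lineage <- config$snp_cluster_traits[[tr]]
      pool <- planted_genes[[lineage]]
      if (length(pool) == 0) next
      genes <- sample(pool, min(config$snps_per_trait, length(pool)))
      gr <- annotation[match(genes, annotation$id)]
      p_lo <- pmax(GenomicRanges::start(gr) - 50000, 1)
      p_hi <- GenomicRanges::end(gr) + 50000
      snps <- rbind(snps, data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = floor(stats::runif(length(genes), p_lo, p_hi)),
        trait = tr, pvalue = 10^-stats::runif(length(genes), 6, 12),
        stringsAsFactors = FALSE))
      trait_gene_map[[tr]] <- genes
    }
    snps <- snps[order(snps$chrom, snps$pos, snps$trait), , drop = FALSE]
    rownames(snps) <- NULL
    list(snps = snps, trait_gene_map = trait_gene_map)
  })
}

#' Generate the GO DAG and gene annotations
#'
#' Builds a rooted is_a DAG (root, `n_go_mid` intermediate terms,
#' `n_go_leaves_per_mid` leaves each). One designated leaf term annotates
#' exactly the planted co-expression module genes; every other leaf
#' annotates a random gene set. Annotations are returned propagated to all
#' ancestors (true-path rule).
#'
#' @param config a [synthetic_config()].
#' @param annotation GRanges from [generate_annotation()] (gene ids).
#' @return list with `dag` (a `GODag`), `gene2term` (propagated data.frame
#'   `gene_id`, `term_id`), and `module_term`.
#' @export
generate_go <- function(config, annotation) {
  config <- validate_synthetic_config(config)
  ps <- planted_sets(config)
  root <- "GO:0000001"
  mids <- sprintf("GO:00100%02d", seq_len(config$n_go_mid))
  leaves <- sprintf("GO:002%04d",
                    seq_len(config$n_go_mid * config$n_go_leaves_per_mid))
  edges <- rbind(
    data.frame(child = mids, parent = root, stringsAsFactors = FALSE),
    data.frame(child = leaves,
               parent = rep(mids, each = config$n_go_leaves_per_mid),
               stringsAsFactors = FALSE))
  dag <- build_go_dag(edges)
  module_term <- leaves[1]

  with_seed(derive_seed(config$seed, "go"), {
    gene_pool <- setdiff(ps$gene_ids, ps$module_genes)
    direct <- data.frame(gene_id = ps$module_genes, term_id = module_term,
                         stringsAsFactors = FALSE)
    for (lf in leaves[-1]) {
      direct <- rbind(direct, data.frame(
        gene_id = sample(gene_pool, config$go_term_size),
        term_id = lf, stringsAsFactors = FALSE))
    }
    term2genes <- propagate_annotations(direct, dag)
    gene2term <- do.call(rbind, lapply(names(term2genes), function(t) {
      g <- term2genes[[t]]
      if (length(g) == 0) return(NULL)
      data.frame(gene_id = g, term_id = t, stringsAsFactors = FALSE)
    }))
    gene2term <- gene2term[order(gene2term$gene_id, gene2term$term_id), ,
                           drop = FALSE]
    rownames(gene2term) <- NULL
    list(dag = dag, gene2term = gene2term, module_term = module_term)
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs all generators with stage seeds derived from `config$seed` and
#' assembles the combined ground truth.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrices`, `detection_p`, `annotation`, `marks`,
#'   `snps`, `go`, `truth`.
#' @export
generate_synthetic_dataset <- function(config) {
  config <- validate_synthetic_config(config)
  expr <- generate_expression(config)
  annotation <- generate_annotation(config)
  marks <- generate_marks(config, annotation, expr$truth)
  snps <- generate_snps(config, annotation, expr$truth)
  go <- generate_go(config, annotation)
  truth <- expr$truth
  truth$enriched_mark_regions <- marks$enriched_regions
  truth$trait_gene_map <- snps$trait_gene_map
  list(matrices = expr$matrices, detection_p = expr$detection_p,
       annotation = annotation, marks = marks, snps = snps$snps, go = go,
       truth = truth)
}
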