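## End-to-end orchestration: presence -> DE -> consensus -> lineage ->
## mark enrichment -> vicinity/trend -> GO attribution -> SNP enrichment,
## from a single config with one root seed, writing plain TSV/JSON artifacts.

#' Pipeline configuration defaults
#'
#' All thresholds and windows default to the values the analysis is defined
#' by: DE at BH-adjusted p < 0.05 with |log2FC| > 1, detection p < 0.01,
#' co-expression |r| > 0.9, GO attribution p < 0.01, SNP filter p <= 1e-5,
#' enhancer/promoter TSS windows of 125 kb / 2.5 kb, lncRNA vicinity
#' 5 kb up / 30 kb down, SNP association +-100 kb, and 10,000 randomization
#' draws.
#'
#' @return named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(de_alpha = 0.05, lfc = 1, detection_alpha = 0.01,
       coexpr_threshold = 0.9, go_alpha = 0.01, snp_p = 1e-5,
       enhancer_window = 125000, promoter_window = 2500,
       lnc_up = 5000, lnc_down = 30000, snp_window = 100000,
       n_iter = 10000, seed = 1,
       mode = "consensus", go_algorithm = "elim",
       refine_rule = "either", lncrna_refine = "none",
       presence_rule = "posterior", dedup_marks = TRUE)
}

#' Validate a pipeline configuration
#'
#' Injects defaults for missing fields, reports every violation (by field
#' name) in a single error, and warns on unknown keys instead of failing
#' (forward compatibility). Never partially applies.
#'
#' @param config named list of overrides (possibly empty).
#' @return the completed, validated configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  chk(in01(cfg$de_alpha), "de_alpha must be in (0,1)")
  chk(in01(cfg$detection_alpha), "detection_alpha must be in (0,1)")
  chk(in01(cfg$go_alpha), "go_alpha must be in (0,1)")
  chk(in01(cfg$snp_p), "snp_p must be in (0,1)")
  chk(is.numeric(cfg$lfc) && cfg$lfc >= 0, "lfc must be >= 0")
  chk(in01(cfg$coexpr_threshold), "coexpr_threshold must be in (0,1)")
  for (w in c("enhancer_window", "promoter_window", "lnc_up", "lnc_down",
              "snp_window"))
    chk(is.numeric(cfg[[w]]) && cfg[[w]] >= 0, paste(w, "must be >= 0"))
  chk(is.numeric(cfg$n_iter) && cfg$n_iter >= 1, "n_iter must be >= 1")
  chk(cfg$mode %in% c("consensus", "seqonly"),
      "mode must be consensus or seqonly")
  chk(cfg$go_algorithm %in% c("elim", "classic"),
      "go_algorithm must be elim or classic")
  chk(cfg$refine_rule %in% c("either", "test", "reference", "both", "none"),
      "refine_rule invalid")
  chk(cfg$lncrna_refine %in% c("either", "test", "reference", "both", "none"),
      "lncrna_refine invalid")
  if (length(errs) > 0)
    stop_validation("invalid pipeline config: ", paste(errs, collapse = "; "))
  cfg
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf("[thlineage] %s", sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes presence calling, differential expression, cross-platform
#' consensus, lineage classification, enhancer/promoter randomization
#' enrichment, the lncRNA vicinity rule and expression trend, co-expression
#' GO attribution and disease-SNP trait enrichment on a dataset (synthetic
#' or read from files), deterministically for a given `config$seed`.
#'
#' @param data list with elements `matrices` (named list of
#'   [expression_matrix()]), optional `detection_p`, `annotation` (GRanges),
#'   `marks`, `snps`, `go`, and optional `truth` (enables the evaluation
#'   block of the report). See [generate_synthetic_dataset()] and
#'   [read_pipeline_inputs()].
#' @param config pipeline configuration (see [validate_config()]).
#' @param out_dir if non-NULL, stage artifacts (TSV) and the report (JSON)
#'   are written there.
#' @param verbose log stage progress to stderr.
#' @return A `PipelineReport` list; see the `evaluation` element for
#'   ground-truth comparisons when `data$truth` is present.
#' @export
run_pipeline <- function(data, config = list(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- validate_config(config)
  ann <- data$annotation
  gene_ids_all <- ann$id[ann$type == "gene"]
  lnc_ids_all <- ann$id[ann$type == "lncRNA"]
  groups <- c("Thp", "Th0", "Th1", "Th2")
  comparisons <- list(c("Thp", "Th0"), c("Thp", "Th1"), c("Thp", "Th2"))

  ## ---- presence ----
  presence <- list(); fits <- list(); vst_values <- NULL; size_factors <- NULL
  for (pf in names(data$matrices)) {
    em <- data$matrices[[pf]]
    if (em$kind == "count") {
      size_factors <- median_of_ratios_size_factors(em$values)
      vst_values <- variance_stabilize(em$values, size_factors)
      vem <- expression_matrix(vst_values, em$design, pf, "intensity")
      fits[[pf]] <- fit_two_component_em(as.vector(vst_values),
                                         seed = derive_seed(cfg$seed, paste0("em_", pf)))
      presence[[pf]] <- call_presence_mixture(vem, fits[[pf]],
                                              rule = cfg$presence_rule)
    } else if (!is.null(data$detection_p) &&
               all(colnames(em$values) %in% colnames(data$detection_p))) {
      presence[[pf]] <- call_presence_detection(
        data$detection_p[rownames(em$values), colnames(em$values)],
        em$design, alpha = cfg$detection_alpha)
    } else {
      fits[[pf]] <- fit_two_component_em(as.vector(em$values),
                                         seed = derive_seed(cfg$seed, paste0("em_", pf)))
      presence[[pf]] <- call_presence_mixture(em, fits[[pf]],
                                              rule = cfg$presence_rule)
    }
    pipeline_log(verbose, "presence [%s]: %d/%d features present somewhere",
                 pf, sum(rowSums(presence[[pf]]) > 0), nrow(presence[[pf]]))
  }

  ## ---- differential expression ----
  gene_tables <- list(); lnc_tables <- list(); count_platform <- NULL
  for (pf in names(data$matrices)) {
    em <- data$matrices[[pf]]
    gene_rows <- intersect(rownames(em$values), gene_ids_all)
    for (cmp in comparisons) {
      if (em$kind == "count") {
        count_platform <- pf
        gem <- expression_matrix(em$values[gene_rows, , drop = FALSE],
                                 em$design, pf, "count")
        tab <- count_de_test(gem, cmp[1], cmp[2], size_factors = size_factors)
        tab <- apply_de_filter(tab, presence[[pf]], alpha = cfg$de_alpha,
                               lfc = cfg$lfc, refine = cfg$refine_rule)
        gene_tables[[paste(pf, cmp[2], sep = ".")]] <- tab
        lnc_rows <- intersect(rownames(em$values), lnc_ids_all)
        if (length(lnc_rows) > 0) {
          lem <- expression_matrix(em$values[lnc_rows, , drop = FALSE],
                                   em$design, pf, "count")
          ltab <- count_de_test(lem, cmp[1], cmp[2],
                                size_factors = size_factors)
          ltab <- apply_de_filter(ltab, presence[[pf]], alpha = cfg$de_alpha,
                                  lfc = cfg$lfc, refine = cfg$lncrna_refine)
          lnc_tables[[paste(pf, cmp[2], sep = ".")]] <- ltab
        }
      } else {
        gem <- expression_matrix(em$values[gene_rows, , drop = FALSE],
                                 em$design, pf, "intensity")
        tab <- moderated_t_test(gem, cmp[1], cmp[2])
        tab <- apply_de_filter(tab, presence[[pf]], alpha = cfg$de_alpha,
                               lfc = cfg$lfc, refine = cfg$refine_rule)
        gene_tables[[paste(pf, cmp[2], sep = ".")]] <- tab
      }
    }
    pipeline_log(verbose, "DE [%s]: done", pf)
  }

  ## ---- consensus + lineage classification ----
  consensus <- build_consensus(gene_tables)
  genes_consensus <- classify_lineage(consensus, mode = "consensus")
  seq_gene_tables <- gene_tables[grep(paste0("^", count_platform, "\\."),
                                      names(gene_tables))]
  genes_seqonly <- classify_lineage(seq_gene_tables, mode = "seqonly")
  lnc_assign <- if (length(lnc_tables) > 0)
    classify_lineage(lnc_tables, mode = "seqonly") else NULL

  gene_assign <- if (cfg$mode == "consensus") genes_consensus else genes_seqonly
  sets <- list(
    Th1 = list(genes = lineage_set(gene_assign, "Th1-specific"),
               lncrnas = if (is.null(lnc_assign)) character(0)
                         else lineage_set(lnc_assign, "Th1-specific")),
    Th2 = list(genes = lineage_set(gene_assign, "Th2-specific"),
               lncrnas = if (is.null(lnc_assign)) character(0)
                         else lineage_set(lnc_assign, "Th2-specific")))
  pipeline_log(verbose, "lineage: Th1 %d/%d, Th2 %d/%d (genes/lncRNAs)",
               length(sets$Th1$genes), length(sets$Th1$lncrnas),
               length(sets$Th2$genes), length(sets$Th2$lncrnas))

  ## universes: features present in >=1 subtype on the count platform
  pres_count <- presence[[count_platform]]
  present_ids <- rownames(pres_count)[rowSums(pres_count) > 0]
  gene_universe <- intersect(present_ids, gene_ids_all)
  lnc_universe <- intersect(present_ids, lnc_ids_all)

  ## ---- enhancer/promoter randomization enrichment ----
  enrichment <- list()
  mark_windows <- c(enhancer = cfg$enhancer_window,
                    promoter = cfg$promoter_window)
  for (lineage in c("Th1", "Th2")) {
    for (cls in c("enhancer", "promoter")) {
      marks <- data$marks[[paste0(cls, "s")]][[lineage]]
      for (ftype in c("genes", "lncrnas")) {
        target <- intersect(sets[[lineage]][[ftype]],
                            if (ftype == "genes") gene_universe else lnc_universe)
        universe_ids <- if (ftype == "genes") gene_universe else lnc_universe
        key <- paste(lineage, cls, ftype, sep = ".")
        if (length(target) == 0 || is.null(marks) ||
            length(universe_ids) <= length(target)) next
        enrichment[[key]] <- randomization_enrichment(
          target, ann[match(universe_ids, ann$id)], marks,
          upstream = mark_windows[[cls]], downstream = mark_windows[[cls]],
          anchor = "tss", strand_aware = FALSE, n_iter = cfg$n_iter,
          seed = derive_seed(cfg$seed, paste0("enrich_", key)))
      }
    }
  }
  pipeline_log(verbose, "enrichment: %d randomization tests", length(enrichment))

  ## ---- lncRNA vicinity + trend ----
  vicinity <- list(); trend <- NULL
  if (!is.null(vst_values)) {
    for (lineage in c("Th1", "Th2")) {
      l_ids <- intersect(sets[[lineage]]$lncrnas, ann$id)
      g_ids <- intersect(sets[[lineage]]$genes, ann$id)
      vicinity[[lineage]] <- lncrna_gene_vicinity(
        ann[match(l_ids, ann$id)], ann[match(g_ids, ann$id)],
        upstream = cfg$lnc_up, downstream = cfg$lnc_down)
    }
    all_pairs <- do.call(rbind, vicinity)
    trend <- pair_correlation_trend(all_pairs, vst_values, vst_values)
  }

  ## ---- biotype tally ----
  biotypes <- classify_biotype(
    unique(c(sets$Th1$lncrnas, sets$Th2$lncrnas)), ann)

  ## ---- co-expression network + GO attribution ----
  network <- NULL; go_attribution <- NULL
  if (!is.null(vst_values) && !is.null(data$go)) {
    lnc_expr <- vst_values[intersect(rownames(vst_values), lnc_ids_all), ,
                           drop = FALSE]
    gene_expr <- vst_values[intersect(rownames(vst_values), gene_universe), ,
                            drop = FALSE]
    network <- coexpression_network(lnc_expr, gene_expr,
                                    threshold = cfg$coexpr_threshold)
    go_attribution <- attribute_terms_to_lncrnas(
      network, data$go$gene2term, data$go$dag, universe = gene_universe,
      algorithm = cfg$go_algorithm, cutoff = cfg$go_alpha)
    pipeline_log(verbose, "GO: %d edges, %d attributions",
                 nrow(network), nrow(go_attribution))
  }

  ## ---- disease-SNP trait enrichment ----
  snp_tables <- list()
  if (!is.null(data$snps)) {
    kept <- filter_snps(data$snps, threshold = cfg$snp_p)
    gene_traits <- associate_genes(
      kept, ann[match(gene_universe, ann$id)], window = cfg$snp_window)
    lnc_traits <- associate_genes(
      kept, ann[match(lnc_universe, ann$id)], window = cfg$snp_window)
    for (lineage in c("Th1", "Th2")) {
      g <- intersect(sets[[lineage]]$genes, gene_universe)
      if (length(g) > 0)
        snp_tables[[paste0(lineage, ".genes")]] <-
          trait_hypergeometric_test(g, gene_traits, gene_universe)
      l <- intersect(sets[[lineage]]$lncrnas, lnc_universe)
      if (length(l) > 0)
        snp_tables[[paste0(lineage, ".lncrnas")]] <-
          trait_hypergeometric_test(l, lnc_traits, lnc_universe)
    }
  }

  report <- structure(list(
    config = cfg,
    n_features = vapply(data$matrices, function(m) nrow(m$values), integer(1)),
    presence_counts = lapply(presence, colSums),
    de_counts = vapply(gene_tables, function(t) sum(t$is_de), integer(1)),
    lineage_sizes = list(
      consensus = c(Th1 = length(lineage_set(genes_consensus, "Th1-specific")),
                    Th2 = length(lineage_set(genes_consensus, "Th2-specific"))),
      seqonly = c(Th1 = length(lineage_set(genes_seqonly, "Th1-specific")),
                  Th2 = length(lineage_set(genes_seqonly, "Th2-specific"))),
      lncrnas = c(Th1 = length(sets$Th1$lncrnas),
                  Th2 = length(sets$Th2$lncrnas))),
    assignments = list(consensus = genes_consensus, seqonly = genes_seqonly,
                       lncrnas = lnc_assign),
    sets = sets, gene_universe = gene_universe, lnc_universe = lnc_universe,
    enrichment = enrichment, vicinity = vicinity, trend = trend,
    biotypes = biotypes, network = network, go_attribution = go_attribution,
    snp_tables = snp_tables,
    presence = presence, fits = fits,
    gene_tables = gene_tables, lnc_tables = lnc_tables,
    consensus = consensus
  ), class = "PipelineReport")

  if (!is.null(data$truth))
    report$evaluation <- evaluate_against_truth(report, data)
  if (!is.null(out_dir)) write_pipeline_artifacts(report, data, out_dir)
  report
}

## ground-truth comparisons for synthetic runs
evaluate_against_truth <- function(report, data) {
  truth <- data$truth
  ann <- data$annotation
  ## presence fidelity on the mixture-called intensity platform
  mix_pf <- names(data$matrices)[vapply(data$matrices, function(m)
    m$kind == "intensity", logical(1))]
  mix_pf <- setdiff(mix_pf, "illumina")[1]
  ev <- list()
  if (!is.na(mix_pf)) {
    calls <- report$presence[[mix_pf]]
    truth_mat <- vapply(colnames(calls), function(g)
      rownames(calls) %in% truth$expressed_features[[g]],
      logical(nrow(calls)))
    ev$presence_sensitivity <- sum(calls & truth_mat) / sum(truth_mat)
    ev$presence_specificity <- sum(!calls & !truth_mat) / sum(!truth_mat)
  }
  ev$f1_th1_genes <- f1_score(report$sets$Th1$genes, truth$th1_genes)
  ev$f1_th2_genes <- f1_score(report$sets$Th2$genes, truth$th2_genes)
  ev$f1_th1_lncrnas <- f1_score(report$sets$Th1$lncrnas, truth$th1_lncrnas)
  ev$f1_th2_lncrnas <- f1_score(report$sets$Th2$lncrnas, truth$th2_lncrnas)

  ## vicinity: geometric recovery (operation on true planted sets) and
  ## pipeline-level recovery (detected among recovered features)
  vp <- truth$vicinity_pairs
  if (nrow(vp) > 0) {
    geo <- rbind(
      lncrna_gene_vicinity(ann[match(truth$th1_lncrnas, ann$id)],
                           ann[match(truth$th1_genes, ann$id)]),
      lncrna_gene_vicinity(ann[match(truth$th2_lncrnas, ann$id)],
                           ann[match(truth$th2_genes, ann$id)]))
    key <- function(d) paste(d$lncrna_id, d$gene_id)
    ev$vicinity_geometric_recall <- mean(key(vp) %in% key(geo))
    det <- do.call(rbind, report$vicinity)
    ev$vicinity_pipeline_recall <-
      if (is.null(det) || nrow(det) == 0) 0 else mean(key(vp) %in% key(det))
  }

  ## planted SNP trait rank (1 = most enriched)
  planted_traits <- names(truth$trait_gene_map)
  if (length(planted_traits) > 0 && length(report$snp_tables) > 0) {
    ranks <- vapply(planted_traits, function(tr) {
      best <- Inf
      for (tab in report$snp_tables)
        if (tr %in% tab$trait) best <- min(best, match(tr, tab$trait))
      best
    }, numeric(1))
    ev$planted_trait_rank <- unname(ranks)
  }

  ## planted GO term attributed to the module lncRNA
  if (!is.null(report$go_attribution)) {
    ev$module_term_attributed <- any(
      report$go_attribution$lncrna_id == truth$module$lncrna &
        report$go_attribution$term_id == truth$module$term)
  }
  ev
}

## plain-text artifacts: every reported number is recomputable from these
write_pipeline_artifacts <- function(report, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  for (pf in names(report$presence))
    write_presence_tsv(report$presence[[pf]], fp(paste0("presence_", pf, ".tsv")))
  for (nm in names(report$gene_tables))
    write_de_tsv(report$gene_tables[[nm]], fp(paste0("de_genes_", nm, ".tsv")))
  for (nm in names(report$lnc_tables))
    write_de_tsv(report$lnc_tables[[nm]], fp(paste0("de_lncrnas_", nm, ".tsv")))
  write_tsv(report$consensus, fp("consensus.tsv"))
  write_tsv(report$assignments$consensus, fp("lineage_consensus.tsv"))
  write_tsv(report$assignments$seqonly, fp("lineage_seqonly.tsv"))
  if (!is.null(report$assignments$lncrnas))
    write_tsv(report$assignments$lncrnas, fp("lineage_lncrnas.tsv"))
  if (!is.null(report$network)) write_tsv(report$network, fp("coexpression_edges.tsv"))
  if (!is.null(report$go_attribution))
    write_tsv(report$go_attribution, fp("go_attribution.tsv"))
  for (nm in names(report$snp_tables))
    write_tsv(report$snp_tables[[nm]], fp(paste0("snp_traits_", nm, ".tsv")))
  jsonlite::write_json(report_summary(report), fp("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Serializable summary of a pipeline report
#'
#' @param report a `PipelineReport`.
#' @return nested list of scalars/vectors suitable for JSON.
#' @export
report_summary <- function(report) {
  list(
    seed = report$config$seed,
    n_features = as.list(report$n_features),
    de_counts = as.list(report$de_counts),
    lineage_sizes = lapply(report$lineage_sizes, as.list),
    enrichment = lapply(report$enrichment, function(e) list(
      observed = e$observed, empirical_p = e$empirical_p, n_iter = e$n_iter,
      null_mean = mean(e$null_counts),
      null_q = as.list(stats::setNames(
        stats::quantile(e$null_counts, c(0.05, 0.5, 0.95)),
        c("q05", "q50", "q95"))))),
    vicinity_pairs = lapply(report$vicinity, nrow),
    trend = if (is.null(report$trend)) NULL else
      report$trend[c("mean_r", "fraction_positive", "n_pairs")],
    biotypes = report$biotypes,
    n_network_edges = if (is.null(report$network)) 0 else nrow(report$network),
    snp_top_traits = lapply(report$snp_tables, function(t)
      utils::head(t[, c("trait", "k", "K", "pvalue")], 5)),
    evaluation = report$evaluation
  )
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  cat(sprintf("  lineage genes (%s): Th1 %d, Th2 %d\n", x$config$mode,
              length(x$sets$Th1$genes), length(x$sets$Th2$genes)))
  cat(sprintf("  lineage lncRNAs: Th1 %d, Th2 %d\n",
              length(x$sets$Th1$lncrnas), length(x$sets$Th2$lncrnas)))
  for (nm in names(x$enrichment))
    cat(sprintf("  enrichment %s: observed %d, p = %.4g\n", nm,
                x$enrichment[[nm]]$observed, x$enrichment[[nm]]$empirical_p))
  if (!is.null(x$evaluation)) {
    cat("  evaluation vs ground truth:\n")
    for (nm in names(x$evaluation))
      cat(sprintf("    %s: %s\n", nm,
                  paste(signif(unlist(x$evaluation[[nm]]), 4), collapse = " ")))
  }
  invisible(x)
}

#' One-command synthetic demonstration
#'
#' Generates the default synthetic dataset (optionally resized) and runs the
#' full pipeline on it; fully deterministic for a given seed.
#'
#' @param out_dir optional output directory for artifacts.
#' @param seed root seed for both generation and analysis.
#' @param synthetic named overrides for [synthetic_config()].
#' @param config named overrides for [validate_config()].
#' @param verbose log stage progress.
#' @return A `PipelineReport` (invisibly if `out_dir` given).
#' @export
run_demo <- function(out_dir = NULL, seed = 1, synthetic = list(),
                     config = list(), verbose = FALSE) {
  syn_cfg <- do.call(synthetic_config, c(list(seed = seed), synthetic))
  data <- generate_synthetic_dataset(syn_cfg)
  cfg <- utils::modifyList(list(seed = seed), config)
  report <- run_pipeline(data, cfg, out_dir = out_dir, verbose = verbose)
  if (is.null(out_dir)) report else invisible(report)
}

#' Read pipeline inputs from files
#'
#' @param expr named list; each element `c(expr = path, samples = path)`.
#' @param detection optional detection-p TSV (feature_id + sample columns).
#' @param annotation GTF path.
#' @param enhancers,promoters BED paths (name field = lineage label).
#' @param snps SNP TSV path.
#' @param go_edges,gene2term GO DAG edge-list and annotation TSV paths
#'   (`go_edges` may also be a minimal OBO file ending in `.obo`).
#' @return a data list accepted by [run_pipeline()].
#' @export
read_pipeline_inputs <- function(expr, detection = NULL, annotation,
                                 enhancers = NULL, promoters = NULL,
                                 snps = NULL, go_edges = NULL,
                                 gene2term = NULL) {
  matrices <- lapply(expr, function(e)
    read_expression_tsv(e[["expr"]], e[["samples"]]))
  names(matrices) <- vapply(matrices, function(m) m$platform, character(1))
  detection_p <- NULL
  if (!is.null(detection)) {
    df <- read_tsv(detection)
    detection_p <- as.matrix(df[, -1, drop = FALSE])
    rownames(detection_p) <- df$feature_id
  }
  marks <- list(enhancers = list(), promoters = list())
  if (!is.null(enhancers)) {
    bed <- read_marks_bed(enhancers)
    marks$enhancers <- split(bed, bed$lineage)
  }
  if (!is.null(promoters)) {
    bed <- read_marks_bed(promoters)
    marks$promoters <- split(bed, bed$lineage)
  }
  go <- NULL
  if (!is.null(go_edges)) {
    dag <- if (grepl("\\.obo$", go_edges)) read_go_obo(go_edges)
           else read_go_edges_tsv(go_edges)
    go <- list(dag = dag, gene2term = read_gene2term_tsv(gene2term))
  }
  list(matrices = matrices, detection_p = detection_p,
       annotation = read_annotation_gtf(annotation), marks = marks,
       snps = if (is.null(snps)) NULL else read_snp_tsv(snps), go = go,
       truth = NULL)
}
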