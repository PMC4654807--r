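## Gene Ontology DAG handling: a minimal rooted is_a DAG with true-path
## annotation propagation, plus classic and elim Fisher enrichment.
## Written in-package: only is_a edges are supported, which is all the
## guilt-by-association attribution needs.

#' Build a GO DAG from child-parent is_a edges
#'
#' @param edges data.frame with columns `child`, `parent` (term ids).
#' @return A `GODag`: list with `terms`, `parents` (list term -> parent ids),
#'   `children`, `root`, `topo_order` (children before parents).
#' @export
build_go_dag <- function(edges) {
  if (!all(c("child", "parent") %in% names(edges)))
    stop_validation("edges needs columns child, parent")
  terms <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop_validation("DAG must have exactly one root, found ", length(roots))
  ## Kahn topological sort starting from the leaves (in-degree counted over
  ## child -> parent edges), so children always precede their parents; a
  ## leftover node means a cycle.
  indeg <- lengths(children)
  queue <- terms[indeg == 0L]
  topo <- character(0)
  while (length(queue) > 0L) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (p in parents[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(terms))
    stop_validation("cycle detected in GO DAG")
  structure(list(terms = terms, parents = parents, children = children,
                 root = roots, topo_order = topo),
            class = "GODag")
}

#' @export
print.GODag <- function(x, ...) {
  cat(sprintf("GODag: %d terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

#' All ancestors of each term (transitive is_a closure, term excluded)
#'
#' @param dag a [build_go_dag()] result.
#' @return named list: term id -> character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$topo_order) {   # parents of t are processed after t, so go up
    ps <- dag$parents[[t]]
    anc[[t]] <- ps
  }
  ## expand bottom-up: process in reverse topo order (parents first)
  for (t in rev(dag$topo_order)) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate gene annotations to ancestor terms (true-path rule)
#'
#' @param gene2term data.frame with columns `gene_id`, `term_id`; terms must
#'   exist in the DAG.
#' @param dag a [build_go_dag()] result.
#' @return named list: term id -> character vector of annotated gene ids
#'   (direct plus inherited from descendants).
#' @export
propagate_annotations <- function(gene2term, dag) {
  unknown <- setdiff(gene2term$term_id, dag$terms)
  if (length(unknown) > 0)
    stop_validation("annotation term(s) not in DAG: ",
                    paste(utils::head(unknown, 3), collapse = ", "))
  anc <- go_ancestors(dag)
  term2genes <- stats::setNames(
    lapply(dag$terms, function(t) character(0)), dag$terms)
  direct <- split(gene2term$gene_id,
                  factor(gene2term$term_id, levels = dag$terms))
  for (t in dag$terms) {
    targets <- c(t, anc[[t]])
    for (a in targets)
      term2genes[[a]] <- c(term2genes[[a]], direct[[t]])
  }
  lapply(term2genes, unique)
}

#' GO term enrichment of a study set (classic and elim Fisher)
#'
#' `classic`: per term, one-sided Fisher exact test (hypergeometric upper
#' tail) on the 2x2 table study/non-study x annotated/not. `elim`: terms are
#' visited children before parents; when a term's p-value falls below
#' `alpha_elim`, its annotated genes are removed from all its ancestors'
#' annotation sets before those are tested, so high-level terms are not
#' carried by their significant descendants.
#'
#' @param study character vector of gene ids, subset of `universe`.
#' @param universe character vector of gene ids.
#' @param gene2term annotation data.frame (`gene_id`, `term_id`) or an
#'   already-propagated term -> genes list.
#' @param dag a [build_go_dag()] result.
#' @param algorithm `"classic"` or `"elim"`.
#' @param alpha_elim elimination threshold for `elim` (default 0.01).
#' @param min_term_size terms annotating fewer universe genes are skipped
#'   (default 3).
#' @return data.frame sorted by p-value: `term_id`, `study_count`,
#'   `study_size`, `term_universe_count`, `universe_size`, `pvalue`,
#'   `algorithm`.
#' @export
go_enrichment <- function(study, universe, gene2term, dag,
                          algorithm = c("classic", "elim"),
                          alpha_elim = 0.01, min_term_size = 3L) {
  algorithm <- match.arg(algorithm)
  study <- unique(study); universe <- unique(universe)
  if (!all(study %in% universe))
    stop_validation("study set must be a subset of the universe")
  term2genes <- if (is.list(gene2term) && !is.data.frame(gene2term))
    gene2term else propagate_annotations(gene2term, dag)
  term2genes <- lapply(term2genes, intersect, universe)
  anc <- go_ancestors(dag)
  N <- length(universe); n <- length(study)
  removed <- stats::setNames(
    lapply(dag$terms, function(t) character(0)), dag$terms)
  rows <- list()
  for (t in dag$topo_order) {
    genes_t <- term2genes[[t]]
    K_full <- length(genes_t)
    if (K_full < min_term_size) next
    if (algorithm == "elim")
      genes_t <- setdiff(genes_t, removed[[t]])
    K <- length(genes_t)
    k <- length(intersect(study, genes_t))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    if (algorithm == "elim" && p < alpha_elim) {
      for (a in anc[[t]])
        removed[[a]] <- unique(c(removed[[a]], term2genes[[t]]))
    }
    rows[[t]] <- data.frame(term_id = t, study_count = k, study_size = n,
                            term_universe_count = K, universe_size = N,
                            pvalue = p, algorithm = algorithm,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), study_count = integer(0),
                      study_size = integer(0), term_universe_count = integer(0),
                      universe_size = integer(0), pvalue = numeric(0),
                      algorithm = character(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$pvalue, out$term_id), , drop = FALSE]
}
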