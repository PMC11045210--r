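# Over-representation analysis of a DEG list against a disease annotation
# map. Only genes that belong to at least one significantly enriched disease
# term survive into feature selection.

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability of observing at least `k` annotated genes in a query of size
#' `n_query` drawn from a universe of `N` genes of which `K` carry the
#' annotation. Computed via [stats::phyper()], which works in log space
#' internally, so extreme overlaps do not underflow.
#'
#' @param k Observed overlap. @param K Term size in the universe.
#' @param n_query Query size. @param N Universe size.
#' @return Upper-tail probability.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n_query, N) {
  if (!all(vapply(list(k, K, n_query, N), is_count, logical(1))))
    stop("all arguments must be non-negative integers")
  if (K > N || n_query > N || k > min(K, n_query))
    stop("need K <= N, n_query <= N, k <= min(K, n_query)")
  stats::phyper(k - 1, K, N - K, n_query, lower.tail = FALSE)
}

#' Propagate gene annotations up an is_a DAG
#'
#' Ontology-true closure: each term's gene set becomes the union of its own
#' genes and those of all its descendants, so genes annotated to a specific
#' disease also count for its ancestors.
#'
#' @param map An [annotation_map()] with acyclic `dag_edges` (a map without
#'   edges is returned unchanged).
#' @return A new `annotation_map` with propagated gene sets.
#' @export
propagate_annotations <- function(map) {
  stopifnot(inherits(map, "annotation_map"))
  edges <- map$dag_edges
  if (is.null(edges) || !nrow(edges)) return(map)
  check_acyclic(edges)
  children_of <- split(edges$child, edges$parent)
  cache <- new.env(parent = emptyenv())
  genes_of <- function(term) {
    if (!is.null(cache[[term]])) return(cache[[term]])
    own <- map$term_to_genes[[term]] %||% character()
    kids <- children_of[[term]] %||% character()
    out <- unique(c(own, unlist(lapply(kids, genes_of), use.names = FALSE)))
    cache[[term]] <- out
    out
  }
  terms <- union(names(map$term_to_genes), unique(c(edges$child, edges$parent)))
  sets <- stats::setNames(lapply(terms, genes_of), terms)
  sets <- sets[lengths(sets) > 0]
  nms <- map$term_names[intersect(names(sets), names(map$term_names))]
  missing <- setdiff(names(sets), names(nms))
  nms[missing] <- missing
  annotation_map(sets, nms, edges)
}

#' Disease-term over-representation analysis
#'
#' One-sided hypergeometric test per term against the given gene universe,
#' BH-adjusted across all tested terms. Terms annotating fewer than
#' `min_term_size` universe genes are skipped so degenerate single-gene
#' tests do not inflate the correction burden.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param map An [annotation_map()].
#' @param universe Character vector of background genes.
#' @param min_term_size Minimum term size in the universe (default 2).
#' @param p_cut Significance threshold stored for downstream filtering
#'   (default 0.05); all tested terms are returned regardless.
#' @return data.frame of class `enrichment_result` with columns `term_id`,
#'   `term_name`, `k`, `K`, `n_query`, `N`, `p_raw`, `p_adj` and a
#'   list-column `member_genes` (the query genes inside the term), sorted by
#'   `p_adj` then `term_id`. Zero rows for an empty query.
#' @export
enrich <- function(query, map, universe, min_term_size = 2, p_cut = 0.05) {
  stopifnot(inherits(map, "annotation_map"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n_query = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  empty$member_genes <- list()
  if (!length(query)) {
    message("empty query: no enrichment computed")
    return(structure(empty, class = c("enrichment_result", "data.frame"), p_cut = p_cut))
  }
  N <- length(universe)
  rows <- lapply(names(map$term_to_genes), function(t) {
    tg <- intersect(map$term_to_genes[[t]], universe)
    K <- length(tg)
    if (K < min_term_size) return(NULL)
    ov <- intersect(query, tg)
    data.frame(term_id = t, term_name = unname(map$term_names[t]) %||% t,
               k = length(ov), K = K, n_query = length(query), N = N,
               p_raw = hypergeom_upper_tail(length(ov), K, length(query), N),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(structure(empty, class = c("enrichment_result", "data.frame"), p_cut = p_cut))
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$member_genes <- lapply(tab$term_id, function(t)
    intersect(query, map$term_to_genes[[t]]))
  tab <- tab[order(tab$p_adj, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("enrichment_result", "data.frame"), p_cut = p_cut)
}

#' Keep only DEGs covered by a significantly enriched term
#'
#' @param deg_genes Ordered character vector of DEG ids (the enrichment
#'   query).
#' @param results An `enrichment_result` from [enrich()].
#' @param p_cut Adjusted-p threshold for a term to count (default 0.05).
#' @return Subsequence of `deg_genes` (original order preserved) of genes in
#'   at least one significant term's overlap.
#' @export
filter_genes_by_enrichment <- function(deg_genes, results, p_cut = 0.05) {
  sig <- results[results$p_adj < p_cut, , drop = FALSE]
  keep <- unique(unlist(sig$member_genes, use.names = FALSE))
  deg_genes[deg_genes %in% keep]
}

#' Write enrichment results to TSV
#'
#' @param results An `enrichment_result`. @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  out <- as.data.frame(results[, setdiff(names(results), "member_genes")])
  out$member_genes <- vapply(results$member_genes, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
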