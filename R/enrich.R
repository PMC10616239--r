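#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: term id, description,
#'   then member ids, tab-separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Build a gene-set collection
#'
#' Restricts every set to the universe and drops sets left empty (with a
#' message).
#'
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of feature ids forming the enrichment
#'   universe (typically all features in the expression matrix under study).
#' @param term_names Optional named character vector of human-readable term
#'   names.
#' @return A list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, term_names = NULL) {
  if (length(universe) == 0) stop_("empty universe")
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(restricted, length, integer(1)) == 0
  if (any(empty)) {
    message(sprintf("dropping %d set(s) empty after universe restriction",
                    sum(empty)))
    restricted <- restricted[!empty]
  }
  if (length(restricted) == 0) stop_("no non-empty sets after restriction")
  structure(list(sets = restricted, universe = universe,
                 term_names = term_names),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query ids using the
#' inclusive upper-tail hypergeometric probability (the same kernel as the
#' shared-miRNA ceRNA test, [hyper_upper_p()]). Query ids outside the
#' universe are dropped with a message.
#'
#' @param query Character vector of feature ids.
#' @param collection A [gene_set_collection()].
#' @param p_threshold Enrichment threshold on the raw p-value (default 0.05).
#' @param adjust_p If `TRUE`, add a BH-adjusted `p_adj` column and use it for
#'   the enrichment call.
#' @return A tibble with columns `term_id`, `term_name`, `overlap_k`,
#'   `set_K`, `query_n`, `universe_N`, `p_value` (plus `p_adj` if requested)
#'   and `enriched`, ordered by p-value.
#' @export
ora <- function(query, collection, p_threshold = 0.05, adjust_p = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    message(sprintf("dropping %d query id(s) outside the universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop_("empty query after universe restriction")
  N <- length(collection$universe)
  n <- length(query)
  res <- tibble::tibble(
    term_id = names(collection$sets),
    term_name = unname((collection$term_names %||%
                          setNames(names(collection$sets),
                                   names(collection$sets)))[names(collection$sets)]),
    overlap_k = unname(vapply(collection$sets,
                              function(s) length(intersect(s, query)),
                              integer(1))),
    set_K = unname(vapply(collection$sets, length, integer(1))),
    query_n = n,
    universe_N = N
  )
  res$p_value <- hyper_upper_p(res$overlap_k, res$set_K, res$query_n, N)
  p_use <- res$p_value
  if (adjust_p) {
    res$p_adj <- p.adjust(res$p_value, "BH")
    p_use <- res$p_adj
  }
  res$enriched <- p_use <= p_threshold
  dplyr::arrange(res, .data$p_value, .data$term_id)
}
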