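#' Tidy a ceRNA network into its edge table
#'
#' @param x A [cerna_network()].
#' @param ... Unused.
#' @return The edge tibble (`source`, `target`, `edge_type`, `statistic`,
#'   `p_value`).
#' @exportS3Method generics::tidy
tidy.cerna_network <- function(x, ...) x$edges

#' One-row summary of a ceRNA network
#'
#' @param x A [cerna_network()].
#' @param ... Unused.
#' @return A one-row tibble with node counts per RNA class and edge counts
#'   per edge type.
#' @exportS3Method generics::glance
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_mirna = sum(x$nodes$rna_class == "miRNA"),
    n_lncrna = sum(x$nodes$rna_class == "lncRNA"),
    n_mrna = sum(x$nodes$rna_class == "mRNA"),
    n_edges = nrow(x$edges),
    n_mirna_target = sum(x$edges$edge_type == "mirna_target"),
    n_cerna_pair = sum(x$edges$edge_type == "cerna_pair")
  )
}

#' Tidy a pipeline result into its final ceRNA pairs
#'
#' @param x A `cerna_pipeline` object from [run_cerna_pipeline()].
#' @param ... Unused.
#' @return The candidate-pair tibble with statistics and the `final` flag.
#' @exportS3Method generics::tidy
tidy.cerna_pipeline <- function(x, ...) {
  out <- x$pairs
  out$shared_mirnas <- NULL
  out
}

#' One-row stage-count summary of a pipeline run
#'
#' @param x A `cerna_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble, one column per pipeline stage count.
#' @exportS3Method generics::glance
glance.cerna_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "stage", values_from = "count")
}
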