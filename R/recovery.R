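#' Evaluate recovery of planted triplets
#'
#' Compares the triplets present in an inferred network against the truth
#' table of a synthetic study. A (lncRNA, miRNA, mRNA) triplet is called in
#' the network when the lncRNA-mRNA `cerna_pair` edge is present together
#' with `mirna_target` edges from the miRNA to both members.
#'
#' @param network A [cerna_network()].
#' @param truth The `truth` element of a [simulate_cerna_data()] result.
#' @return A list with `recall` (recovered planted triplets / planted),
#'   `false_discovery_proportion` (non-planted called triplets / called; 0
#'   when none are called), `called` (tibble of called triplets) and
#'   `confusion` (tibble with `n_planted`, `n_called`, `tp`, `fp`, `fn`).
#' @export
evaluate_recovery <- function(network, truth) {
  called <- network_triplets(network)
  planted <- truth$triplets[, c("lncrna_id", "mirna_id", "mrna_id")]
  tp <- nrow(dplyr::inner_join(called, planted,
                               by = c("lncrna_id", "mirna_id", "mrna_id")))
  recall <- if (nrow(planted) == 0) NA_real_ else tp / nrow(planted)
  fdp <- if (nrow(called) == 0) 0 else (nrow(called) - tp) / nrow(called)
  list(
    recall = recall,
    false_discovery_proportion = fdp,
    called = called,
    confusion = tibble::tibble(
      n_planted = nrow(planted), n_called = nrow(called),
      tp = tp, fp = nrow(called) - tp, fn = nrow(planted) - tp
    )
  )
}

#' Enumerate the triplets of a ceRNA network
#'
#' @param network A [cerna_network()].
#' @return A tibble with columns `lncrna_id`, `mirna_id`, `mrna_id`, one row
#'   per (final pair, shared miRNA) combination present in the network.
#' @export
network_triplets <- function(network) {
  e <- network$edges
  pairs <- e[e$edge_type == "cerna_pair", c("source", "target")]
  mt <- e[e$edge_type == "mirna_target", c("source", "target")]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(lncrna_id = character(), mirna_id = character(),
                          mrna_id = character()))
  }
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    l <- pairs$source[i]; g <- pairs$target[i]
    shared <- intersect(mt$source[mt$target == l], mt$source[mt$target == g])
    if (length(shared) == 0) return(NULL)
    tibble::tibble(lncrna_id = l, mirna_id = shared, mrna_id = g)
  })
  dplyr::arrange(out, .data$lncrna_id, .data$mirna_id, .data$mrna_id)
}
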