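#' Spearman screen for miRNA-ceRNA edges
#'
#' Evaluates the Spearman rank correlation (average ranks for ties) between
#' each miRNA and each of its predicted targets over all samples of both
#' groups, and retains edges with `rho <= rho_threshold` — the negative
#' co-expression expected of a miRNA and the ceRNAs it represses.
#'
#' Only (miRNA, target) pairs present in `relations` are evaluated. Pairs
#' involving a constant expression vector are skipped with a warning.
#'
#' @param mirna_expr [expression_matrix()] for the miRNA layer.
#' @param cerna_expr [expression_matrix()] for the candidate ceRNA layer
#'   (lncRNA or mRNA); must share the sample set of `mirna_expr`.
#' @param relations Target-relation tibble (`regulator_id` = miRNA id,
#'   `target_id` = ceRNA id).
#' @param rho_threshold Retention threshold on Spearman rho (default -0.7,
#'   inclusive).
#' @return A tibble with columns `mirna_id`, `cerna_id`, `cerna_class`,
#'   `spearman_rho`, one row per retained edge.
#' @export
spearman_screen <- function(mirna_expr, cerna_expr, relations,
                            rho_threshold = -0.7) {
  mv <- expr_values(mirna_expr)
  cv <- expr_values(cerna_expr)
  if (!identical(colnames(mv), colnames(cv))) {
    stop_("miRNA and ceRNA matrices must share an identical sample set")
  }
  rel <- relations[relations$regulator_id %in% rownames(mv) &
                     relations$target_id %in% rownames(cv), , drop = FALSE]
  rel <- dplyr::distinct(rel[, c("regulator_id", "target_id")])
  if (nrow(rel) == 0) {
    return(tibble::tibble(mirna_id = character(), cerna_id = character(),
                          cerna_class = character(), spearman_rho = numeric()))
  }
  mr <- t(apply(mv, 1, rank))
  cr <- t(apply(cv, 1, rank))
  rho <- vapply(seq_len(nrow(rel)), function(i) {
    a <- mr[rel$regulator_id[i], ]
    b <- cr[rel$target_id[i], ]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(rho)) {
    warn_("%d pair(s) skipped in Spearman screen (constant expression vector)",
          sum(is.na(rho)))
  }
  keep <- !is.na(rho) & rho <= rho_threshold
  out <- tibble::tibble(
    mirna_id = rel$regulator_id[keep],
    cerna_id = rel$target_id[keep],
    cerna_class = expr_layer(cerna_expr),
    spearman_rho = rho[keep]
  )
  dplyr::arrange(out, .data$mirna_id, .data$cerna_id)
}

#' Pearson screen for candidate ceRNA pairs
#'
#' Computes the Pearson correlation of each candidate lncRNA-mRNA pair over
#' all samples and keeps pairs with `r` strictly greater than `r_threshold`
#' ("greater than" is strict: a pair at exactly the threshold is rejected).
#' Pairs involving a constant vector are skipped with a warning.
#'
#' @param lnc_expr,mrna_expr [expression_matrix()] objects over identical
#'   sample sets.
#' @param candidates Tibble (or data frame) with columns `lncrna_id` and
#'   `mrna_id`.
#' @param r_threshold Strict lower bound on Pearson r (default 0.9).
#' @return A tibble with columns `lncrna_id`, `mrna_id`, `pearson_r` for the
#'   surviving pairs.
#' @export
pearson_screen <- function(lnc_expr, mrna_expr, candidates, r_threshold = 0.9) {
  lv <- expr_values(lnc_expr)
  gv <- expr_values(mrna_expr)
  if (!identical(colnames(lv), colnames(gv))) {
    stop_("lncRNA and mRNA matrices must share an identical sample set")
  }
  cand <- dplyr::distinct(tibble::as_tibble(candidates)[, c("lncrna_id", "mrna_id")])
  cand <- cand[cand$lncrna_id %in% rownames(lv) & cand$mrna_id %in% rownames(gv), ]
  if (nrow(cand) == 0) {
    return(tibble::tibble(lncrna_id = character(), mrna_id = character(),
                          pearson_r = numeric()))
  }
  r <- vapply(seq_len(nrow(cand)), function(i) {
    a <- lv[cand$lncrna_id[i], ]
    b <- gv[cand$mrna_id[i], ]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(r)) {
    warn_("%d pair(s) skipped in Pearson screen (constant expression vector)",
          sum(is.na(r)))
  }
  keep <- !is.na(r) & r > r_threshold
  out <- tibble::tibble(lncrna_id = cand$lncrna_id[keep],
                        mrna_id = cand$mrna_id[keep],
                        pearson_r = r[keep])
  dplyr::arrange(out, .data$lncrna_id, .data$mrna_id)
}

#' Hypergeometric shared-miRNA test for ceRNA pairs
#'
#' For each candidate lncRNA-mRNA pair, tests whether the two transcripts
#' share more miRNA regulators than expected by chance. With a universe of
#' `N` miRNAs, `K` of which have a retained (post-Spearman) edge to the
#' lncRNA and `n` to the mRNA, and `k` shared, the p-value is the inclusive
#' upper tail `P(X >= k)` of the hypergeometric distribution
#' (see [hyper_upper_p()]).
#'
#' @param pairs Tibble of candidate pairs (columns `lncrna_id`, `mrna_id`,
#'   typically the output of [pearson_screen()]).
#' @param edges Retained miRNA-ceRNA edges from [spearman_screen()].
#' @param universe Character vector of miRNA ids forming the universe;
#'   defaults to all miRNAs appearing in `edges`.
#' @return `pairs` with added columns `shared_mirnas` (list column),
#'   `k_shared`, `K_lnc`, `n_mrna`, `N_universe` and `hypergeom_p`.
#' @export
hypergeom_shared_test <- function(pairs, edges, universe = NULL) {
  universe <- universe %||% unique(edges$mirna_id)
  if (length(universe) == 0) stop_("empty miRNA universe")
  edges <- edges[edges$mirna_id %in% universe, , drop = FALSE]
  by_cerna <- split(edges$mirna_id, edges$cerna_id)
  N <- length(universe)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    lset <- unique(by_cerna[[pairs$lncrna_id[i]]]) %||% character()
    gset <- unique(by_cerna[[pairs$mrna_id[i]]]) %||% character()
    shared <- intersect(lset, gset)
    if (length(lset) > N || length(gset) > N) {
      stop_("regulator set larger than universe for pair %s-%s",
            pairs$lncrna_id[i], pairs$mrna_id[i])
    }
    list(shared = shared, k = length(shared), K = length(lset), n = length(gset))
  })
  out <- tibble::as_tibble(pairs)
  out$shared_mirnas <- purrr::map(res, "shared")
  out$k_shared <- purrr::map_int(res, "k")
  out$K_lnc <- purrr::map_int(res, "K")
  out$n_mrna <- purrr::map_int(res, "n")
  out$N_universe <- N
  out$hypergeom_p <- hyper_upper_p(out$k_shared, out$K_lnc, out$n_mrna, N)
  out
}

#' Construct a ceRNA network object
#'
#' Validates the node and edge tables of a ceRNA network: every edge endpoint
#' must be a node, no self edges, no duplicated (source, target, edge_type).
#'
#' @param nodes Tibble with columns `id` and `rna_class`
#'   (`"miRNA"`/`"lncRNA"`/`"mRNA"`).
#' @param edges Tibble with columns `source`, `target`, `edge_type`
#'   (`"mirna_target"` or `"cerna_pair"`), `statistic`, `p_value`.
#' @return A list of class `cerna_network` with elements `nodes` and `edges`.
#' @export
cerna_network <- function(nodes, edges) {
  nodes <- dplyr::arrange(tibble::as_tibble(nodes), .data$id)
  edges <- dplyr::arrange(tibble::as_tibble(edges),
                          .data$edge_type, .data$source, .data$target)
  if (anyDuplicated(nodes$id)) stop_("duplicated node id")
  ends <- c(edges$source, edges$target)
  if (!all(ends %in% nodes$id)) {
    stop_("edge endpoint(s) missing from nodes: %s",
          paste(setdiff(ends, nodes$id), collapse = ", "))
  }
  if (any(edges$source == edges$target)) stop_("self edges are not allowed")
  if (anyDuplicated(edges[, c("source", "target", "edge_type")])) {
    stop_("duplicated edge")
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cls <- table(x$nodes$rna_class)
  typ <- table(x$edges$edge_type)
  cat(sprintf("<cerna_network> %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
              nrow(x$edges),
              paste(sprintf("%s: %d", names(typ), typ), collapse = ", ")))
  invisible(x)
}

#' Assemble the final ceRNA network
#'
#' Keeps ceRNA pairs whose shared-miRNA hypergeometric p-value is at most
#' `p_threshold` (the final pairs), then builds the network of interacting
#' triplets: one `cerna_pair` edge per final pair, and `mirna_target` edges
#' only from miRNAs shared by a final pair to the members of that pair.
#' Node and edge order is deterministic.
#'
#' @param edges Retained miRNA-ceRNA edges from [spearman_screen()].
#' @param pairs Candidate pairs with `hypergeom_p` (from
#'   [hypergeom_shared_test()]).
#' @param p_threshold Hypergeometric significance threshold (default 0.05).
#' @return A [cerna_network()].
#' @export
assemble_network <- function(edges, pairs, p_threshold = 0.05) {
  final <- pairs[pairs$hypergeom_p <= p_threshold, , drop = FALSE]
  if (nrow(final) == 0) {
    return(cerna_network(
      tibble::tibble(id = character(), rna_class = character()),
      tibble::tibble(source = character(), target = character(),
                     edge_type = character(), statistic = numeric(),
                     p_value = numeric())
    ))
  }
  pair_edges <- tibble::tibble(
    source = final$lncrna_id, target = final$mrna_id,
    edge_type = "cerna_pair",
    statistic = final$pearson_r, p_value = final$hypergeom_p
  )
  rho_of <- setNames(edges$spearman_rho, paste(edges$mirna_id, edges$cerna_id))
  mir_edges <- purrr::map_dfr(seq_len(nrow(final)), function(i) {
    shared <- final$shared_mirnas[[i]]
    if (length(shared) == 0) return(NULL)
    src <- rep(shared, 2)
    tgt <- rep(c(final$lncrna_id[i], final$mrna_id[i]), each = length(shared))
    tibble::tibble(
      source = src, target = tgt,
      edge_type = "mirna_target",
      statistic = unname(rho_of[paste(src, tgt)]),
      p_value = NA_real_
    )
  })
  if (nrow(mir_edges) > 0) {
    mir_edges <- dplyr::distinct(mir_edges, .data$source, .data$target,
                                 .keep_all = TRUE)
  }
  all_edges <- dplyr::bind_rows(mir_edges, pair_edges)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = final$lncrna_id, rna_class = "lncRNA"),
    tibble::tibble(id = final$mrna_id, rna_class = "mRNA"),
    if (nrow(mir_edges) > 0)
      tibble::tibble(id = unique(mir_edges$source), rna_class = "miRNA")
  )
  nodes <- dplyr::distinct(nodes)
  cerna_network(nodes, all_edges)
}
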