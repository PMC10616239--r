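#' Run the full ceRNA inference pipeline
#'
#' Executes the complete chain on three expression layers: (1) two-group DE
#' screen on each layer; (2) restriction of the miRNA target-relation table
#' to differentially expressed regulators and targets; (3) Spearman screen of
#' miRNA-lncRNA and miRNA-mRNA edges; (4) candidate ceRNA pairs = DE lncRNA
#' x DE mRNA pairs sharing at least one retained miRNA; (5) Pearson screen;
#' (6) hypergeometric shared-miRNA test; (7) network assembly. The stage-count
#' report lists feature/edge/pair counts at every stage.
#'
#' Correlations are computed on the supplied expression values over all
#' samples of both groups pooled; supply normalized matrices (FPKM/TPM) to
#' mirror the standard workflow.
#'
#' @param mrna_expr,lnc_expr,mirna_expr [expression_matrix()] objects over an
#'   identical sample set.
#' @param design Design tibble (`sample_id`, `group` in `HIGH`/`LOW`).
#' @param relations Target-relation tibble linking miRNA regulators
#'   (`regulator_id`) to lncRNA or mRNA targets (`target_id`), e.g. from
#'   [predict_seed_targets()]/[intersect_predictions()].
#' @param fc_threshold,p_threshold DE screen thresholds (defaults 1.5, 0.05).
#' @param de_method DE test method, see [de_screen()].
#' @param rho_threshold Spearman retention threshold (default -0.7).
#' @param r_threshold Pearson strict lower bound (default 0.9).
#' @param hyper_p_threshold Hypergeometric significance threshold
#'   (default 0.05).
#' @param universe `"retained"` (miRNAs with at least one post-Spearman edge;
#'   default) or `"all_expressed"` (all miRNAs in `mirna_expr`).
#' @param adjust_hyper_p If `TRUE`, apply Benjamini-Hochberg adjustment to the
#'   hypergeometric p-values before thresholding.
#' @return An object of class `cerna_pipeline`: a list with elements
#'   `network` ([cerna_network()]), `de` (per-layer DE tibbles), `edges`
#'   (retained miRNA-ceRNA edges), `pairs` (tested candidate pairs with
#'   statistics and a `final` flag), `report` (stage-count tibble) and
#'   `params`.
#' @export
run_cerna_pipeline <- function(mrna_expr, lnc_expr, mirna_expr, design,
                               relations,
                               fc_threshold = 1.5, p_threshold = 0.05,
                               de_method = "welch_log",
                               rho_threshold = -0.7, r_threshold = 0.9,
                               hyper_p_threshold = 0.05,
                               universe = c("retained", "all_expressed"),
                               adjust_hyper_p = FALSE) {
  universe <- match.arg(universe)
  de <- list(
    mRNA = de_screen(mrna_expr, design, fc_threshold, p_threshold, de_method),
    lncRNA = de_screen(lnc_expr, design, fc_threshold, p_threshold, de_method),
    miRNA = de_screen(mirna_expr, design, fc_threshold, p_threshold, de_method)
  )
  sig <- lapply(de, function(d) d$feature_id[d$significant])

  rel_de <- relations[relations$regulator_id %in% sig$miRNA &
                        relations$target_id %in% c(sig$lncRNA, sig$mRNA), ,
                      drop = FALSE]

  sub_expr <- function(x, ids) {
    keep <- x$feature_id %in% ids
    if (!any(keep)) return(NULL)
    expression_matrix(x[keep, , drop = FALSE], expr_layer(x), expr_unit(x))
  }
  mir_de_expr <- sub_expr(mirna_expr, sig$miRNA)
  lnc_de_expr <- sub_expr(lnc_expr, sig$lncRNA)
  mrna_de_expr <- sub_expr(mrna_expr, sig$mRNA)

  empty_edges <- tibble::tibble(mirna_id = character(), cerna_id = character(),
                                cerna_class = character(),
                                spearman_rho = numeric())
  edges <- dplyr::bind_rows(
    if (!is.null(mir_de_expr) && !is.null(lnc_de_expr))
      spearman_screen(mir_de_expr, lnc_de_expr, rel_de, rho_threshold)
    else empty_edges,
    if (!is.null(mir_de_expr) && !is.null(mrna_de_expr))
      spearman_screen(mir_de_expr, mrna_de_expr, rel_de, rho_threshold)
    else empty_edges
  )

  el <- edges[edges$cerna_class == "lncRNA", c("mirna_id", "cerna_id")]
  em <- edges[edges$cerna_class == "mRNA", c("mirna_id", "cerna_id")]
  candidates <- dplyr::distinct(
    dplyr::inner_join(el, em, by = "mirna_id",
                      suffix = c("_l", "_m"),
                      relationship = "many-to-many")[, c("cerna_id_l", "cerna_id_m")]
  )
  names(candidates) <- c("lncrna_id", "mrna_id")

  surv <- pearson_screen(lnc_expr, mrna_expr, candidates, r_threshold)

  mir_universe <- switch(universe,
    retained = unique(edges$mirna_id),
    all_expressed = expr_features(mirna_expr)
  )
  if (nrow(surv) > 0 && length(mir_universe) > 0) {
    pairs <- hypergeom_shared_test(surv, edges, mir_universe)
    p_use <- if (adjust_hyper_p) p.adjust(pairs$hypergeom_p, "BH") else pairs$hypergeom_p
    if (adjust_hyper_p) pairs$hypergeom_p_adj <- p_use
    pairs$final <- p_use <= hyper_p_threshold
  } else {
    pairs <- surv
    pairs$shared_mirnas <- list()
    pairs$k_shared <- integer()
    pairs$K_lnc <- integer()
    pairs$n_mrna <- integer()
    pairs$N_universe <- integer()
    pairs$hypergeom_p <- numeric()
    pairs$final <- logical()
  }

  network <- assemble_network(edges,
                              {p <- pairs; p[p$final, , drop = FALSE]},
                              p_threshold = 1)

  report <- tibble::tibble(
    stage = c("de_mrna", "de_lncrna", "de_mirna", "relations_de",
              "spearman_edges", "candidate_pairs", "pearson_pairs",
              "final_pairs", "network_nodes", "network_edges"),
    count = c(sum(de$mRNA$significant), sum(de$lncRNA$significant),
              sum(de$miRNA$significant), nrow(rel_de), nrow(edges),
              nrow(candidates), nrow(surv), sum(pairs$final),
              nrow(network$nodes), nrow(network$edges))
  )
  params <- list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 de_method = de_method, rho_threshold = rho_threshold,
                 r_threshold = r_threshold,
                 hyper_p_threshold = hyper_p_threshold, universe = universe,
                 adjust_hyper_p = adjust_hyper_p)
  structure(list(network = network, de = de, edges = edges, pairs = pairs,
                 report = report, params = params),
            class = "cerna_pipeline")
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("<cerna_pipeline>\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-16s %d\n", x$report$stage[i], x$report$count[i]))
  }
  invisible(x)
}
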