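#' Volcano plot of a differential expression screen
#'
#' @param object A `cerna_de` tibble from [de_screen()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 p, colored by call.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_de <- function(object, ...) {
  fc <- attr(object, "fc_threshold") %||% 1.5
  pth <- attr(object, "p_threshold") %||% 0.05
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(pth), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (HIGH / LOW)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ceRNA network
#'
#' Nodes are colored by RNA class; miRNA-target edges are drawn solid and
#' ceRNA co-regulation edges dotted, following the usual rendering of such
#' regulation maps.
#'
#' @param object A [cerna_network()].
#' @param seed Layout seed (Fruchterman-Reingold), for reproducible plots.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_network <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  g <- igraph::graph_from_data_frame(
    object$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = object$nodes$id)
  )
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  layout <- tibble::tibble(id = igraph::V(g)$name,
                           x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(object$nodes, layout, by = "id")
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges, layout, by = c("source" = "id")),
    layout, by = c("target" = "id"), suffix = c("", "_end")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_end, yend = .data$y_end,
                   linetype = .data$edge_type),
      colour = "grey50", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$rna_class),
      size = 3
    ) +
    ggplot2::scale_linetype_manual(values = c(mirna_target = "solid",
                                              cerna_pair = "dotted")) +
    ggplot2::scale_colour_manual(values = c(miRNA = "#7b3294",
                                            lncRNA = "#008837",
                                            mRNA = "#c2a5cf")) +
    ggplot2::labs(colour = NULL, linetype = NULL) +
    ggplot2::theme_void()
}

#' Stage-count bar chart of a pipeline run
#'
#' @param object A `cerna_pipeline` object from [run_cerna_pipeline()].
#' @param ... Unused.
#' @return A ggplot of feature/edge/pair counts surviving each stage.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_pipeline <- function(object, ...) {
  rep <- object$report
  rep$stage <- factor(rep$stage, levels = rev(rep$stage))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}
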