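#' Deviation histogram of significant interactions
#'
#' Histogram of the observed/expected growth ratio for the significant
#' records, colored by interaction class, with dashed guides at the
#' strong-interaction cutoff (default +/- 20% from expectation).
#'
#' @param object An `sga_interactions` object.
#' @param strong_cutoff Position of the dashed guides. Default 0.20.
#' @param binwidth Histogram bin width. Default 0.02.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sga_interactions
#' @export
autoplot.sga_interactions <- function(object, strong_cutoff = 0.20,
                                      binwidth = 0.02, ...) {
  sig <- dplyr::filter(tidy(object), .data$class != "none",
                       is.finite(.data$deviation_ratio))
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$deviation_ratio,
                                    fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 1) +
    ggplot2::geom_vline(xintercept = c(1 - strong_cutoff, 1 + strong_cutoff),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_fill_manual(
      values = c(enhancing = "#c23b22", suppressing = "#3b6fc2")) +
    ggplot2::labs(x = "observed / expected growth",
                  y = "significant interactions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a genetic-interaction network
#'
#' Draws the force-directed layout with per-condition edges colored by
#' interaction class and nodes colored by community (when present).
#' Requires [layout_network()] to have been applied.
#'
#' @param object An `sga_network` with layout coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sga_network
#' @export
autoplot.sga_network <- function(object, ...) {
  if (is.null(object$nodes$x)) {
    abort("run layout_network() before plotting")
  }
  nodes <- object$nodes
  edges <- object$edges |>
    dplyr::left_join(nodes[c("gene", "x", "y")],
                     by = c(gene_a = "gene")) |>
    dplyr::left_join(nodes[c("gene", "x", "y")],
                     by = c(gene_b = "gene"), suffix = c("", "end"))
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$class),
      alpha = 0.5)
  }
  aes_nodes <- if (is.null(nodes$community)) {
    ggplot2::aes(x = .data$x, y = .data$y)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y,
                 fill = factor(.data$community))
  }
  p +
    ggplot2::geom_point(data = nodes, aes_nodes, shape = 21, size = 3) +
    ggplot2::scale_colour_manual(
      values = c(enhancing = "#c23b22", suppressing = "#3b6fc2")) +
    ggplot2::labs(colour = "interaction", fill = "community") +
    ggplot2::theme_void()
}

#' Heatmap of growth fold changes across conditions
#'
#' Tile map of a fold-change table (strains by conditions), the standard
#' way to eyeball which carbon sources perturb which mutants.
#'
#' @param fold_changes Output of [fold_change_table()].
#' @param metric Which fold-change column to draw. Default
#'   `"fold_max_amplitude"`.
#' @return A ggplot object.
#' @export
plot_fold_change <- function(fold_changes,
                             metric = "fold_max_amplitude") {
  if (!metric %in% names(fold_changes)) {
    abort(sprintf("column '%s' not found", metric))
  }
  ggplot2::ggplot(fold_changes,
                  ggplot2::aes(x = .data$condition, y = .data$strain_id,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
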