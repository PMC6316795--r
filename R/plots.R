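#' Plot an ROC curve with its convex hull
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object: empirical ROC (solid), convex hull (dashed),
#'   chance diagonal, and the Youden-optimal operating point.
#' @export
autoplot.roc_result <- function(object, ...) {
  op <- object$operating_point
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_line(data = object$hull, linetype = "dashed",
                       colour = "firebrick") +
    ggplot2::annotate("point", x = 1 - op["specificity"],
                      y = op["sensitivity"], shape = 21, size = 3,
                      fill = "firebrick") +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("AUC %.3f, AUCCH %.3f (%d%% CI %.3f-%.3f)",
                      object$auc, object$aucch, round(100 * object$level),
                      object$ci[1], object$ci[2])
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of the null AUCCH values with the observed
#'   value marked. A null centred well above 0.5 signals a procedure able
#'   to fit noise (overfitting capacity).
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$aucch)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Null AUCCH (label permutations)", y = "Count",
                  title = sprintf("Observed %.3f; null %.3f +/- %.3f; p = %.3g",
                                  object$observed, object$null_mean,
                                  object$null_sd, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot the Markov neighborhood of a fitted network
#'
#' @param object A `cgbn_network`.
#' @param neighborhood_only Restrict to the phenotype's Markov neighborhood
#'   (default `TRUE`; the full network can be large).
#' @param ... Unused.
#' @return A ggplot of nodes and directed edges; edge width is proportional
#'   to the edge's log Bayes factor.
#' @export
autoplot.cgbn_network <- function(object, neighborhood_only = TRUE, ...) {
  edges <- object$edges
  if (neighborhood_only && !is.null(object$phenotype)) {
    mn <- markov_neighborhood(object)
    keep <- c(object$phenotype, mn$node)
    edges <- edges[edges$from %in% keep & edges$to %in% keep, ]
  }
  if (nrow(edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  seg <- edges %>%
    left_join(nodes, by = c("from" = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(nodes, by = c("to" = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linewidth = .data$log_bf),
      colour = "grey55",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), name = "log BF") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = .data$name == (object$phenotype %||% "")),
      size = 3, show.legend = FALSE
    ) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 2.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue")) +
    ggplot2::theme_void()
}

#' Hyperparameter selection curve
#'
#' Cross-validated AUCCH against the tuned hyperparameter (PLS component
#' count or log Bayes-factor threshold).
#'
#' @param curve A tibble with the hyperparameter in the first column and an
#'   `aucch` column (as returned by [select_n_components()] or
#'   [select_bf_threshold()]).
#' @param selected Optional selected value to mark.
#' @return A ggplot object.
#' @export
plot_selection_curve <- function(curve, selected = NULL) {
  xnm <- names(curve)[1]
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data[[xnm]], y = .data$aucch)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xnm, y = "Cross-validated AUCCH") +
    ggplot2::theme_minimal()
  if (!is.null(selected)) {
    p <- p + ggplot2::geom_vline(xintercept = selected, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
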