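#' Plot latent-scale preference effects
#'
#' Dot-and-interval plot of the per-level effects from
#' [preference_summary()] (or the `effects` table of a report section):
#' one panel per variable, reference levels at 0, intervals at +/- 1.96
#' standard errors.
#'
#' @param effects Tibble with columns `variable`, `level`, `estimate`,
#'   `std_error` (an optional `factor` column facets by cluster).
#' @return A ggplot object.
#' @export
plot_preference_effects <- function(effects) {
  effects <- tibble::as_tibble(effects)
  p <- ggplot2::ggplot(effects,
         ggplot2::aes(x = .data$estimate, y = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent-scale effect (vs reference level)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if ("factor" %in% names(effects)) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$variable),
                            ggplot2::vars(.data$factor),
                            scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y")
  }
}

#' Plot dominance weights
#'
#' Box plot of per-participant dominance weights by variable; when cluster
#' labels are supplied the panels are split by cluster.
#'
#' @param weights Output of [dominance_weights()].
#' @param labels Optional tibble (`participant_id`, `cluster`).
#' @return A ggplot object.
#' @export
plot_dominance_weights <- function(weights, labels = NULL) {
  weights <- tibble::as_tibble(weights)
  if (!is.null(labels)) {
    weights <- dplyr::inner_join(
      weights, tibble::as_tibble(labels)[c("participant_id", "cluster")],
      by = "participant_id")
  }
  p <- ggplot2::ggplot(weights,
         ggplot2::aes(x = .data$variable, y = .data$weight)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "dominance weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
  if (!is.null(labels)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cluster))
  }
  p
}

#' Plot a factor loading matrix
#'
#' Tile plot of participants x factors loadings with flagged exemplars
#' outlined.
#'
#' @param solution A [q_factor_analysis()] solution.
#' @return A ggplot object.
#' @export
plot_loadings <- function(solution) {
  stopifnot(inherits(solution, "qfactor_solution"))
  td <- tidy(solution)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$factor,
                                   y = .data$participant_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(data = dplyr::filter(td, .data$flagged),
                       fill = NA, colour = "black", linewidth = 0.7) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' @method autoplot ordered_probit
#' @export
autoplot.ordered_probit <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::filter(td, .data$type == "coefficient")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent-scale estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot qfactor_solution
#' @export
autoplot.qfactor_solution <- function(object, ...) {
  plot_loadings(object)
}
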