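#' Plot a gradient along the rostro-caudal axis
#'
#' Scatter of gradient values against the anterior-posterior world
#' coordinate, one panel per hemisphere, colored by the rostral/caudal
#' partition.
#'
#' @param object a `gradient_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gradient_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$value, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::scale_colour_manual(values = c(rostral = "#c0392b", caudal = "#2980b9")) +
    ggplot2::labs(x = "anterior-posterior coordinate (mm)",
                  y = "gradient value (0 = caudal, 1 = rostral)",
                  colour = NULL,
                  title = sprintf("Dominant connectopic gradient (%s)", object$source)) +
    ggplot2::theme_minimal()
}

#' Plot per-parameter partial Spearman correlations
#'
#' Bar chart of the post hoc parameter correlations from a sliding-window
#' or per-year analysis, marking parameters significant after FDR
#' adjustment.
#'
#' @param object an `lc_window_analysis` or `lc_age_analysis`.
#' @param alpha significance level applied to the adjusted p-values.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lc_window_analysis <- function(object, alpha = 0.05, ...) {
  plot_param_correlations(object$correlations, alpha)
}

#' @rdname autoplot.lc_window_analysis
#' @export
autoplot.lc_age_analysis <- function(object, alpha = 0.05, ...) {
  plot_param_correlations(object$correlations, alpha)
}

plot_param_correlations <- function(correlations, alpha) {
  df <- dplyr::mutate(correlations,
                      significant = .data$p_adjusted < alpha,
                      parameter = factor(.data$parameter, levels = .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$rho,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70"),
                               name = sprintf("FDR p < %.2g", alpha)) +
    ggplot2::labs(x = NULL, y = "partial Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot bootstrap group-comparison parameter distributions
#'
#' Violin plots of the bootstrap trend-surface parameter distributions for
#' the two groups.
#'
#' @param object an `lc_group_comparison`.
#' @param parameters subset of parameter names to show (default all 18).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lc_group_comparison <- function(object, parameters = NULL, ...) {
  grp_names <- names(object$params) %||% c("group1", "group2")
  df <- purrr::map2_dfr(object$params, grp_names, function(m, g) {
    tibble::as_tibble(m) |>
      dplyr::mutate(group = g) |>
      tidyr::pivot_longer(-"group", names_to = "parameter", values_to = "value")
  })
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8), scale = "width") +
    ggplot2::labs(x = NULL, y = "trend-surface coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
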