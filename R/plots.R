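#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Arrhenius plot of a linear fit
#'
#' Points are the fitted observations in Arrhenius coordinates; the line
#' is the core-range regression, annotated with the apparent activation
#' energy and its 68% confidence half-width.
#'
#' @param object an `arrhenius_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot arrhenius_fit
autoplot.arrhenius_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_T, y = .data$ln_rate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      slope = object$slope_K, intercept = object$intercept
    ) +
    ggplot2::labs(
      x = expression(1 / T ~ (K^-1)),
      y = "ln(rate / min⁻¹)",
      title = sprintf(
        "Ea = %.1f ± %.1f kJ/mol (68%% CI, n = %d)",
        object$Ea_kJ, object$ci68_Ea_kJ, object$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Composite prediction in Arrhenius coordinates
#'
#' @param object a `composite_prediction`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot composite_prediction
autoplot.composite_prediction <- function(object, ...) {
  pred <- object$prediction |>
    dplyr::mutate(inv_T = 1 / celsius_to_kelvin(.data$temperature_C))
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$inv_T, y = .data$lnk)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = expression(1 / T ~ (K^-1)),
      y = "ln(composite rate / min⁻¹)",
      title = sprintf("Tangent Ea = %.1f kJ/mol", object$tangent_Ea_kJ)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of mean interval CVs
#'
#' Visualises the reproducibility screen: each tile is the mean
#' coefficient of variation (%) of one (start, end) interval across
#' temperatures.
#'
#' @param cv_tbl long CV table from [cv_matrix()].
#' @param scores optional score ordering for the axes.
#' @return A ggplot object.
#' @export
plot_cv_matrix <- function(cv_tbl, scores = NULL) {
  stopifnot(is.data.frame(cv_tbl))
  if (!is.null(scores)) {
    cv_tbl <- cv_tbl |>
      dplyr::mutate(
        start_code = factor(.data$start_code, levels = scores),
        end_code = factor(.data$end_code, levels = scores)
      )
  }
  ggplot2::ggplot(
    cv_tbl,
    ggplot2::aes(x = .data$end_code, y = .data$start_code,
                 fill = .data$mean_cv_pct)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$mean_cv_pct), "",
                                  sprintf("%.0f", .data$mean_cv_pct))),
      size = 3
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "mean CV (%)") +
    ggplot2::labs(x = "end score", y = "start score") +
    ggplot2::theme_minimal()
}
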