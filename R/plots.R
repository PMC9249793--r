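# ggplot2 displays for the main result types.

#' Plot the BIC restart distributions per cluster number
#'
#' Boxplots of the BIC across random restarts for each candidate k; a
#' compact box means the fit is insensitive to initialization. The selected
#' k is highlighted.
#'
#' @param object A `bic_assessment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bic_assessment <- function(object, ...) {
  df <- object$samples |>
    dplyr::mutate(selected = .data$k == object$k_selected)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$k), y = .data$bic, fill = .data$selected
  )) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "grey80")) +
    ggplot2::labs(
      x = "number of clusters k", y = "BIC (250 restarts)",
      title = "Cluster-number assessment: BIC restart stability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranked biomarker models in accuracy/stability space
#'
#' @param object A `ranked_models` tibble from [composite_rank()].
#' @param ... Unused.
#' @return A ggplot of mean accuracy vs Dice stability, top models
#'   highlighted.
#' @export
autoplot.ranked_models <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$dice, y = .data$mean_accuracy,
    colour = .data$top, shape = .data$selector
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#d95f02", `FALSE` = "grey60"),
      name = "top ranked"
    ) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(
      x = "Dice stability", y = "mean test accuracy",
      title = "Biomarker models: accuracy vs selection stability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ensemble class probabilities per exposure
#'
#' @param object An `ensemble_prediction` tibble.
#' @param ... Unused.
#' @return A stacked-bar ggplot of NoL/M/H probabilities per exposure.
#' @export
autoplot.ensemble_prediction <- function(object, ...) {
  cls <- intersect(c("NoL", "M", "MH", "H"), names(object))
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(cls),
      names_to = "class", values_to = "probability"
    ) |>
    dplyr::mutate(class = factor(.data$class, levels = cls))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$exposure, y = .data$probability, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      NoL = "#1a9850", M = "#fee08b", MH = "#fc8d59", H = "#d73027"
    )[cls]) +
    ggplot2::labs(
      x = NULL, y = "ensemble class probability",
      title = "Hazard class probabilities per exposure"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot observed vs fitted neutrophil counts
#'
#' @param object A `count_regression`.
#' @param ... Unused.
#' @return A ggplot of observed vs fitted log-scale counts.
#' @export
autoplot.count_regression <- function(object, ...) {
  df <- tibble(
    observed = object$fit$model$.y,
    fitted = object$fit$fitted.values
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(colour = "#7570b3", size = 2.5) +
    ggplot2::labs(
      x = sprintf("fitted log(count + %g)", object$offset),
      y = sprintf("observed log(count + %g)", object$offset),
      title = sprintf("Neutrophil count regression (R² = %.2f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
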