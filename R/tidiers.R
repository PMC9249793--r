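# broom-style tidiers for the package's fitted objects.

#' Tidy a biomarker model
#'
#' One row per evaluation repeat with the test accuracy and the size of the
#' subset selected on that repeat.
#'
#' @param x A `biomarker_model`.
#' @param ... Unused.
#' @return A tibble with columns `repeat`, `accuracy`, `n_features`.
#' @export
tidy.biomarker_model <- function(x, ...) {
  tibble(
    `repeat` = seq_along(x$accuracies),
    accuracy = x$accuracies,
    n_features = if (is.null(x$feature_sets)) {
      length(x$features)
    } else {
      lengths(x$feature_sets)
    }
  )
}

#' Glance at a biomarker model
#'
#' @param x A `biomarker_model`.
#' @param ... Unused.
#' @return A one-row tibble: selector, layer, subset size, mean accuracy
#'   with 95% CI, and Dice stability.
#' @export
glance.biomarker_model <- function(x, ...) {
  tibble(
    layer = x$layer, selector = x$selector,
    n_features = length(x$features),
    mean_accuracy = x$mean_accuracy, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    dice = x$stability
  )
}

#' Tidy a BIC assessment
#'
#' @param x A `bic_assessment`.
#' @param ... Unused.
#' @return The long tibble of per-restart BIC values (`k`, `restart`,
#'   `loglik`, `bic`).
#' @export
tidy.bic_assessment <- function(x, ...) x$samples

#' Glance at a BIC assessment
#'
#' @param x A `bic_assessment`.
#' @param ... Unused.
#' @return One-row tibble with the selected k and its mean/sd BIC.
#' @export
glance.bic_assessment <- function(x, ...) {
  row <- x$summary[x$summary$k == x$k_selected, ]
  tibble(
    k_selected = x$k_selected,
    mean_bic = row$mean_bic, sd_bic = row$sd_bic, cv_bic = row$cv_bic
  )
}

#' Tidy a count regression
#'
#' @param x A `count_regression`.
#' @param ... Passed to the `lm` tidier machinery (unused).
#' @return Coefficient table: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.count_regression <- function(x, ...) {
  s <- quiet_lm_summary(x$fit)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' Glance at a count regression
#'
#' @param x A `count_regression`.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `adj_r_squared`, `sigma`,
#'   `n_markers`, `offset`, `n`.
#' @export
glance.count_regression <- function(x, ...) {
  s <- quiet_lm_summary(x$fit)
  tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, n_markers = length(x$markers),
    offset = x$offset, n = length(x$fit$fitted.values)
  )
}
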