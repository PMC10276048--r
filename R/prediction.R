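#' Mean predicted severity probabilities
#'
#' Averages each observation's simulated severity probabilities over the
#' dataset.  Evaluating a model on another subgroup's data is the
#' out-of-sample prediction simulation: the random coefficients are rebuilt
#' from the *target* data's own mean- and variance-shifter values, so both
#' the means and the variances of the random parameters are fully accounted
#' for.
#'
#' @param fit A fitted [fit_mixed_logit()] model.
#' @param data Crash tibble to predict (defaults to the fitting data).
#' @param k Draws; defaults to the fit's estimation setting.
#' @return Tibble `severity`, `mean_prob`; the means sum to one.
#' @export
mean_predicted_probabilities <- function(fit, data = fit$data, k = fit$k) {
  probs <- simulate_probabilities(data, fit$spec, fit$estimates, k = k,
                                  discard = fit$discard)
  tibble::tibble(
    severity = factor(fit$spec$alternatives, levels = fit$spec$alternatives),
    mean_prob = unname(colMeans(as.matrix(probs)))
  )
}

#' Out-of-sample vs within-sample prediction comparison
#'
#' Predicts `data` twice: with the `base` model's parameters (out-of-sample)
#' and with the `within` model's parameters (within-sample, normally the
#' model fitted to `data` itself), and differences the mean severity
#' probabilities.  A positive difference means the base model over-predicts
#' that severity relative to the within model.  Differences always sum to
#' zero across severities because each probability set sums to one.
#'
#' @param base The base (forecasting) fitted model.
#' @param within The within-sample fitted model.
#' @param data Crash tibble to predict; defaults to `within`'s fitting data.
#' @param k Draws (default: `base`'s estimation setting).
#' @return A tibble of class `"prediction_comparison"`: `severity`,
#'   `out_of_sample`, `within_sample`, `difference`.
#' @export
compare_predictions <- function(base, within, data = within$data,
                                k = base$k) {
  oos <- mean_predicted_probabilities(base, data, k = k)
  wis <- mean_predicted_probabilities(within, data, k = k)
  out <- tibble::tibble(
    severity = oos$severity,
    out_of_sample = oos$mean_prob,
    within_sample = wis$mean_prob,
    difference = oos$mean_prob - wis$mean_prob
  )
  class(out) <- c("prediction_comparison", class(out))
  out
}

#' Temporal forecast matrix
#'
#' Each earlier-period model forecasts each later period's data, compared to
#' that later period's own model — the forward-in-time cells of the usual
#' temporal prediction-difference table (with three periods: first to second,
#' first to third, second to third).
#'
#' @param fits Named list of fitted models, one per period; names are period
#'   labels in chronological order.
#' @param datasets Named list of crash tibbles with the same names.
#' @param k Draws (default: first fit's setting).
#' @return Tibble with columns `base`, `forecast` and the
#'   [compare_predictions()] columns, one row per (pair, severity).
#' @export
temporal_forecast_matrix <- function(fits, datasets, k = fits[[1]]$k) {
  periods <- names(fits)
  stopifnot(length(periods) >= 2, identical(sort(periods),
                                            sort(names(datasets))))
  rows <- list()
  for (i in seq_along(periods)) {
    for (jj in seq_along(periods)) {
      if (jj <= i) next
      cmp <- compare_predictions(fits[[periods[i]]], fits[[periods[jj]]],
                                 datasets[[periods[jj]]], k = k)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(base = periods[i], forecast = periods[jj]), cmp)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
autoplot.prediction_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$severity,
                                       y = .data$difference)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL,
                  y = "Out-of-sample minus within-sample mean probability") +
    ggplot2::theme_minimal()
}
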