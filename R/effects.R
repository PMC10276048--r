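#' Average marginal effect of one binary covariate
#'
#' For every observation, the simulated severity probabilities are computed
#' with the covariate forced to 1 and forced to 0 (all other covariates held
#' fixed), differenced, and averaged over all observations:
#' `ME = (1/m) * sum_j [P_j(n) | X = 1  -  P_j(n) | X = 0]`.
#'
#' The *same* draw matrix is used for both covariate states, so quasi-random
#' noise cancels exactly in the difference.  If the toggled covariate is also
#' a heterogeneity-in-mean or -variance shifter of a random coefficient, the
#' toggle propagates through both channels.
#'
#' @param fit A fitted [fit_mixed_logit()] model.
#' @param covariate Name of a binary covariate appearing in the model.
#' @param data Crash tibble to average over; defaults to the fitting data.
#' @return One-row tibble: `covariate` plus one effect column per severity
#'   level.  The effects always sum to zero across severities.
#' @export
marginal_effect <- function(fit, covariate, data = fit$data) {
  if (!covariate %in% spec_covariates(fit$spec)) {
    stop("covariate '", covariate, "' does not appear in the model spec",
         call. = FALSE)
  }
  mf1 <- build_model_frame(fit$spec, dplyr::mutate(data, "{covariate}" := 1))
  mf0 <- build_model_frame(fit$spec, dplyr::mutate(data, "{covariate}" := 0))
  draws <- if (length(mf1$random_terms) > 0L) {
    default_draws(mf1, k = fit$k, discard = fit$discard)
  }
  p1 <- mixl_engine(fit$estimates, mf1, draws, want_probs = TRUE)$probs
  p0 <- mixl_engine(fit$estimates, mf0, draws, want_probs = TRUE)$probs
  eff <- colMeans(p1 - p0)
  out <- tibble::tibble(covariate = covariate)
  out[fit$spec$alternatives] <- as.list(eff)
  out
}

#' Average marginal effects for every covariate in the model
#'
#' One row per distinct covariate entering any utility function, in the
#' layout of the usual marginal-effect summary tables (one column per
#' severity level).  Deterministic given the fit's draw settings.
#'
#' @inheritParams marginal_effect
#' @param covariates Covariates to include; defaults to every covariate with
#'   a utility term (shifter-only covariates excluded).
#' @return A tibble of class `"marginal_effects"`.
#' @export
marginal_effects_table <- function(fit, data = fit$data, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- unique(setdiff(fit$spec$terms$covariate, "constant"))
  }
  out <- dplyr::bind_rows(
    purrr::map(covariates, function(cv) marginal_effect(fit, cv, data))
  )
  class(out) <- c("marginal_effects", class(out))
  out
}

#' @export
autoplot.marginal_effects <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"covariate",
                              names_to = "severity", values_to = "effect")
  long$severity <- factor(long$severity, levels = unique(long$severity))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$effect, y = .data$covariate,
                                     fill = .data$severity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Average marginal effect on probability", y = NULL,
                  fill = "Severity") +
    ggplot2::theme_minimal()
}
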