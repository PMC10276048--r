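#' Log-likelihood of a fitted model transferred to other data
#'
#' Evaluates the simulated log-likelihood of `data` under the fitted model's
#' specification with its converged parameter values held fixed — no
#' re-estimation.  Fresh Halton draws are built for the target data with the
#' fit's own draw settings, so a model evaluated on its own data reproduces
#' its `llbeta` exactly.
#'
#' @param fit A fitted [fit_mixed_logit()] model (the "B" model).
#' @param data Crash tibble (the "A" data); must contain every covariate of
#'   the fit's spec.
#' @return Scalar log-likelihood `LL(beta_BA)`.
#' @export
evaluate_transferred <- function(fit, data) {
  simulated_loglik(data, fit$spec, fit$estimates, k = fit$k,
                   discard = fit$discard)
}

#' Likelihood-ratio transferability / temporal-instability test
#'
#' Tests whether the parameters of model B describe dataset A:
#' `chi2 = -2 * [LL(beta_BA) - LL(beta_A)]`, where `LL(beta_BA)` evaluates
#' B's converged parameters on A's data ([evaluate_transferred()]) and
#' `LL(beta_A)` is a free refit of B's specification on A.  The statistic is
#' chi-squared with degrees of freedom equal to the number of parameters in
#' the transferred specification; the reported confidence is the chi-squared
#' CDF in percent.  A high confidence rejects the hypothesis that the two
#' subgroups share parameters.
#'
#' The free refit is initialised at the transferred parameter values (which
#' makes `chi2 >= 0` structural up to optimiser tolerance) and cross-checked
#' from the default cold start; the better optimum is kept.
#'
#' @param fit The "B" model, a fitted [fit_mixed_logit()].
#' @param data The "A" crash tibble.
#' @param cold_start Also refit from the default start and keep the better
#'   optimum (default `TRUE`).
#' @param ... Passed to the refitting [fit_mixed_logit()] call.
#' @return A one-row tibble of class `"lr_test"`: `chi_sq`, `dof`,
#'   `confidence` (percent), `ll_restricted`, `ll_free`, `refit_converged`,
#'   and the refit in list-column `refit`.
#' @export
lr_transferability_test <- function(fit, data, cold_start = TRUE, ...) {
  ll_restricted <- evaluate_transferred(fit, data)
  refit <- fit_mixed_logit(data, fit$spec, k = fit$k, discard = fit$discard,
                           start = fit$estimates, se = FALSE, ...)
  if (cold_start) {
    refit_cold <- fit_mixed_logit(data, fit$spec, k = fit$k,
                                  discard = fit$discard, se = FALSE, ...)
    if (refit_cold$llbeta > refit$llbeta) refit <- refit_cold
  }
  if (!refit$converged) {
    warning("free refit did not converge; test result flagged", call. = FALSE)
  }
  chi_sq <- -2 * (ll_restricted - refit$llbeta)
  dof <- fit$k_params
  out <- tibble::tibble(
    chi_sq = chi_sq,
    dof = dof,
    confidence = 100 * stats::pchisq(max(chi_sq, 0), df = dof),
    ll_restricted = ll_restricted,
    ll_free = refit$llbeta,
    refit_converged = refit$converged,
    refit = list(refit)
  )
  class(out) <- c("lr_test", class(out))
  out
}

#' Pairwise matrix of likelihood-ratio tests
#'
#' Runs [lr_transferability_test()] for each ordered (model B, data A) pair,
#' e.g. all ordered period pairs within a seatbelt group for the temporal-
#' instability matrix, or restrained-vs-unrestrained within each period for
#' the transferability matrix.  Self-pairs are excluded.
#'
#' @param fits Named list of fitted models.
#' @param datasets Named list of crash tibbles; names must match `fits`.
#' @param pairs Optional two-column data frame / tibble with columns `model`
#'   (B) and `data` (A) selecting ordered pairs; defaults to all ordered
#'   off-diagonal pairs.
#' @param ... Passed to [lr_transferability_test()].
#' @return Tibble with one row per pair: `model`, `data`, the [lr_test
#'   columns][lr_transferability_test()], and `cell`, the conventional
#'   `"chi2 (dof) [confidence%]"` rendering.
#' @export
lr_test_matrix <- function(fits, datasets, pairs = NULL, ...) {
  stopifnot(!is.null(names(fits)), !is.null(names(datasets)))
  if (is.null(pairs)) {
    pairs <- expand.grid(model = names(fits), data = names(datasets),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$model != pairs$data, , drop = FALSE]
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    b <- pairs$model[i]; a <- pairs$data[i]
    res <- lr_transferability_test(fits[[b]], datasets[[a]], ...)
    dplyr::bind_cols(tibble::tibble(model = b, data = a), res)
  })
  out <- dplyr::bind_rows(rows)
  out$cell <- format_lr_cell(out$chi_sq, out$dof, out$confidence)
  out
}

#' Render a likelihood-ratio cell as "chi2 (dof) [confidence%]"
#'
#' Confidence is reported to two decimals (truncated, matching the usual
#' table convention); values above 99.99 print as `">99.99"`.
#'
#' @param chi_sq,dof,confidence Vectors from [lr_test_matrix()].
#' @return Character vector.
#' @export
format_lr_cell <- function(chi_sq, dof, confidence) {
  conf <- ifelse(confidence > 99.99, ">99.99",
                 sprintf("%.2f", trunc(confidence * 100) / 100))
  sprintf("%.2f (%d) [%s%%]", chi_sq, as.integer(dof), conf)
}
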