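#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted mixed logit model
#'
#' @param x A [fit_mixed_logit()] object.
#' @param conf_level Level for the Wald confidence interval columns.
#' @param ... Unused.
#' @return One row per parameter: `term`, `block`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.  Dispersion rows
#'   (`block == "rand_sd"`) report the unconstrained estimate; its magnitude
#'   is the baseline standard deviation.
#' @export
tidy.mixl_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  pt <- param_table(x$spec)
  tibble::tibble(
    term = pt$name,
    block = pt$block,
    estimate = unname(x$estimates),
    std.error = unname(x$std_err),
    statistic = unname(x$t_stat),
    p.value = unname(x$p_value),
    conf.low = unname(x$estimates - z * x$std_err),
    conf.high = unname(x$estimates + z * x$std_err)
  )
}

#' Model-level summary of a fitted mixed logit
#'
#' @param x A [fit_mixed_logit()] object.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `k`, `logLik`, `null.logLik`,
#'   `mcfadden.r2`, `AIC`, `draws`, `converged`, `iterations`.
#' @export
glance.mixl_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    k = x$k_params,
    logLik = x$llbeta,
    null.logLik = x$ll0,
    mcfadden.r2 = mcfadden_r2(x$ll0, x$llbeta),
    AIC = model_aic(x$llbeta, x$k_params),
    draws = x$k,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' @export
logLik.mixl_fit <- function(object, ...) {
  structure(object$llbeta, df = object$k_params, nobs = object$n,
            class = "logLik")
}

#' @export
print.mixl_fit <- function(x, ...) {
  cat(fit_report(x), sep = "\n")
  invisible(x)
}

#' @export
autoplot.mixl_fit <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object, conf_level = conf_level)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Coefficient estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
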