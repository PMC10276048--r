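#' Fit a mixed logit severity model by simulated maximum likelihood
#'
#' Maximises the simulated log-likelihood — the logit kernel averaged over
#' `k` Halton draws per observation — by BFGS quasi-Newton iteration.
#' Random coefficients follow
#' `beta_i = beta + Theta' M_i + |sigma| * exp(omega' SD_i) * nu_i`,
#' so covariates in `M_i` shift the coefficient's mean and covariates in
#' `SD_i` scale its standard deviation.  The dispersion parameter `sigma` is
#' stored unconstrained and interpreted through `|sigma|` (its sign is not
#' identified).  Standard errors come from the inverse numerical Hessian of
#' the negative log-likelihood at the optimum.
#'
#' @param data A crash tibble (see [validate_crash_data()]).
#' @param spec A [severity_spec()].
#' @param k Halton draws per observation; the study default is 1000.  Smaller
#'   values (100-250) are adequate for experimentation.
#' @param discard Initial Halton points skipped per base (default 100).
#' @param start Optional named start vector; defaults to zeros with baseline
#'   dispersions at 0.1.
#' @param gradient `"analytic"` (default; exact, fast) or `"numeric"`
#'   (central finite differences, kept as an independent cross-check).
#' @param gtol Convergence criterion: the fit is flagged converged when the
#'   infinity norm of the per-observation score (`max |grad| / N`) falls
#'   below `gtol` at the optimiser's final iterate.
#' @param se Compute standard errors (skip for speed in loops).
#' @param restarts Maximum number of BFGS restarts from the last iterate when
#'   the iteration budget is exhausted before the gradient criterion is met.
#' @param control Passed to [stats::optim()] after defaults
#'   `maxit = 1000, reltol = 1e-12`.
#' @return An object of class `"mixl_fit"`; see [tidy.mixl_fit()] and
#'   [glance.mixl_fit()] for tidy accessors.  Non-convergence is reported via
#'   the `converged` flag, never silently.
#' @export
#' @examples
#' set.seed(1)
#' truth <- example_truth()
#' crashes <- simulate_crashes(truth, n = 500, seed = 7)
#' fit <- fit_mixed_logit(crashes, truth$spec, k = 50)
#' glance(fit)
fit_mixed_logit <- function(data, spec, k = 1000, discard = 100, start = NULL,
                            gradient = c("analytic", "numeric"),
                            gtol = 1e-5, se = TRUE, restarts = 2,
                            control = list()) {
  gradient <- match.arg(gradient)
  mf <- build_model_frame(spec, data)
  n_rand <- length(mf$random_terms)
  draws <- if (n_rand > 0L) default_draws(mf, k = k, discard = discard)
  pt <- mf$param_table

  if (is.null(start)) {
    start <- params_template(spec)
    start[pt$block == "rand_sd"] <- 0.1
  } else {
    start <- check_params(start, spec)
  }

  # fn and gr share one engine evaluation via a small cache
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) {
      return(cache$res)
    }
    res <- mixl_engine(theta, mf, draws, want_grad = (gradient == "analytic"))
    cache$theta <- theta
    cache$res <- res
    res
  }
  negll <- function(theta) -evaluate(theta)$ll
  neggr <- if (gradient == "analytic") {
    function(theta) -evaluate(theta)$grad
  } else {
    NULL  # optim's own central differences via ndeps
  }

  control <- utils::modifyList(
    list(maxit = 1000, reltol = 1e-12,
         ndeps = rep(1e-6, length(start))), control)
  opt <- stats::optim(start, fn = negll, gr = neggr, method = "BFGS",
                      control = control)
  # restart from the last iterate while the iteration budget was the only
  # stopping reason (standard polish for slow quasi-Newton tails)
  tries <- 0L
  while (opt$convergence == 1L && tries < restarts) {
    opt <- stats::optim(opt$par, fn = negll, gr = neggr, method = "BFGS",
                        control = control)
    tries <- tries + 1L
  }

  final <- mixl_engine(opt$par, mf, draws, want_grad = TRUE)
  grad_norm <- max(abs(final$grad)) / mf$n
  converged <- opt$convergence == 0L && grad_norm < gtol

  std_err <- rep(NA_real_, nrow(pt))
  vcov <- NULL
  se_ok <- FALSE
  if (se) {
    hess <- try(stats::optimHess(
      opt$par, fn = negll,
      gr = if (gradient == "analytic") neggr else NULL,
      control = control), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      vc <- try(solve(hess), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
        vcov <- vc
        std_err <- sqrt(diag(vc))
        se_ok <- TRUE
      }
    }
    if (!se_ok) {
      warning("Hessian singular or not positive definite; ",
              "standard errors unavailable", call. = FALSE)
    }
  }

  estimates <- stats::setNames(opt$par, pt$name)
  tstat <- ifelse(is.na(std_err) | std_err <= 0, NA_real_,
                  estimates / std_err)
  structure(list(
    spec = spec,
    estimates = estimates,
    std_err = stats::setNames(std_err, pt$name),
    t_stat = stats::setNames(tstat, pt$name),
    p_value = stats::setNames(2 * stats::pnorm(-abs(tstat)), pt$name),
    vcov = vcov,
    ll0 = null_loglik(mf$n, mf$j),
    llbeta = final$ll,
    n = mf$n,
    k_params = nrow(pt),
    k = k, discard = discard,
    converged = converged,
    iterations = opt$counts[["function"]],
    grad_norm = grad_norm,
    n_floored = final$n_floored,
    data = data
  ), class = "mixl_fit")
}

#' Equal-shares null log-likelihood
#'
#' `LL(0) = -N ln(J)`: the log-likelihood when every alternative is predicted
#' with equal probability `1/J`.  This is the null used in the McFadden
#' pseudo R-squared for these models (e.g. `N = 773, J = 3` gives -849.227).
#'
#' @param n Number of observations.
#' @param j Number of alternatives (default 3 severity levels).
#' @return Scalar log-likelihood.
#' @export
null_loglik <- function(n, j = 3) {
  stopifnot(n >= 1, j >= 2)
  -n * log(j)
}

#' McFadden pseudo R-squared
#'
#' @param ll0 Null log-likelihood (negative).
#' @param llbeta Log-likelihood at convergence.
#' @return `1 - llbeta / ll0`.
#' @export
mcfadden_r2 <- function(ll0, llbeta) {
  stopifnot(ll0 < 0)
  1 - llbeta / ll0
}

#' Akaike information criterion
#'
#' @param llbeta Log-likelihood at convergence.
#' @param k Number of estimated parameters.
#' @return `-2 * llbeta + 2 * k`.
#' @export
model_aic <- function(llbeta, k) {
  stopifnot(k >= 1)
  -2 * llbeta + 2 * k
}

#' Share of a random-coefficient distribution above zero
#'
#' For a random coefficient with estimated mean and dispersion, the fraction
#' of the population with a positive coefficient — the standard
#' interpretation aid for random parameters (e.g. a normal coefficient with
#' mean 0.233 and SD 2.082 is positive for 54.46% of drivers).
#'
#' @param mean Estimated mean (location for `"lognormal"`).
#' @param dispersion Estimated standard deviation / spread (positive).
#' @param distribution Mixing distribution name.
#' @param sign For `"lognormal"`: the coefficient's sign.
#' @return Fraction in `[0, 1]`.
#' @export
random_share_split <- function(mean, dispersion, distribution = "normal",
                               sign = 1) {
  distribution <- match.arg(distribution, .mixing_distributions)
  if (dispersion == 0) {
    message("zero dispersion: coefficient is degenerate at its mean")
    return(as.numeric(mean > 0))
  }
  stopifnot(dispersion > 0)
  switch(distribution,
    normal = stats::pnorm(mean / dispersion),
    # uniform on [mean - d, mean + d]
    uniform = min(1, max(0, (mean + dispersion) / (2 * dispersion))),
    # symmetric triangular on [mean - d, mean + d]
    triangular = {
      z <- max(-1, min(1, -mean / dispersion))  # 0 in standardised units
      1 - (if (z <= 0) (z + 1)^2 / 2 else 1 - (1 - z)^2 / 2)
    },
    lognormal = as.numeric(sign > 0)
  )
}

#' Simulated probabilities for every observation
#'
#' Averages the multinomial-logit kernel over the draw matrix at the supplied
#' parameters; rows sum to one.  With no random terms this is the exact
#' closed-form multinomial logit probability.
#'
#' @param data A crash tibble.
#' @param spec A [severity_spec()].
#' @param params Named parameter vector (see [param_table()] for the layout).
#' @param k,discard Draw settings, used only if `draws` is not given.
#' @param draws Optional pre-built [make_draw_matrix()] for this data.
#' @return Tibble with one row per observation and one probability column per
#'   severity level.
#' @export
simulate_probabilities <- function(data, spec, params, k = 1000, discard = 100,
                                   draws = NULL) {
  mf <- build_model_frame(spec, data)
  params <- check_params(params, spec)
  if (length(mf$random_terms) > 0L && is.null(draws)) {
    draws <- default_draws(mf, k = k, discard = discard)
  }
  res <- mixl_engine(params, mf, draws, want_probs = TRUE)
  probs <- tibble::as_tibble(as.data.frame(res$probs))
  names(probs) <- spec$alternatives
  probs
}

#' Simulated log-likelihood at given parameters
#'
#' @inheritParams simulate_probabilities
#' @return Scalar: the sum over observations of the log of the simulated
#'   probability of the observed outcome.
#' @export
simulated_loglik <- function(data, spec, params, k = 1000, discard = 100,
                             draws = NULL) {
  mf <- build_model_frame(spec, data)
  params <- check_params(params, spec)
  if (length(mf$random_terms) > 0L && is.null(draws)) {
    draws <- default_draws(mf, k = k, discard = discard)
  }
  mixl_engine(params, mf, draws)$ll
}

#' Compare mixing distributions for the random coefficients
#'
#' Refits the model once per candidate distribution (every random term takes
#' the candidate) and tabulates fit, mirroring the usual model-selection
#' table.  A fit that errors or does not converge is recorded as
#' `"fail to converge"`, not raised.
#'
#' @param data A crash tibble.
#' @param spec A [severity_spec()] with at least one random term.
#' @param distributions Candidate distribution names.
#' @param lognormal_sign Sign for the lognormal candidate.
#' @param ... Passed to [fit_mixed_logit()].
#' @return Tibble with one row per distribution: `distribution`, `logLik`,
#'   `AIC`, `converged`, `status`, and the fitted object in list-column
#'   `fit`.
#' @export
compare_mixing_distributions <- function(data, spec,
                                         distributions = .mixing_distributions,
                                         lognormal_sign = 1, ...) {
  if (nrow(spec$random) == 0L) {
    stop("spec has no random terms; nothing to compare", call. = FALSE)
  }
  rows <- purrr::map(distributions, function(d) {
    sp <- spec
    sp$random$distribution <- rep(d, nrow(sp$random))
    if (d == "lognormal") sp$random$sign <- rep(lognormal_sign, nrow(sp$random))
    fit <- tryCatch(fit_mixed_logit(data, sp, ...), error = function(e) NULL)
    ok <- !is.null(fit) && isTRUE(fit$converged)
    tibble::tibble(
      distribution = d,
      logLik = if (is.null(fit)) NA_real_ else fit$llbeta,
      AIC = if (is.null(fit)) NA_real_ else model_aic(fit$llbeta, fit$k_params),
      converged = ok,
      status = if (ok) "converged" else "fail to converge",
      fit = list(fit)
    )
  })
  dplyr::bind_rows(rows)
}
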