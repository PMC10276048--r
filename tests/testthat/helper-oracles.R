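# Independent oracles and small fixtures shared across test files.
# The oracles are deliberately written as plain per-record loops over the
# parameter names, sharing no code with the package's vectorised engine.

oracle_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# closed-form multinomial logit probabilities for one record, looping over
# the spec's terms by name
oracle_mnl_probs <- function(spec, params, record) {
  v <- stats::setNames(numeric(length(spec$alternatives)), spec$alternatives)
  tm <- spec$terms
  for (i in seq_len(nrow(tm))) {
    x <- if (tm$covariate[i] == "constant") 1 else record[[tm$covariate[i]]]
    nm <- if (tm$covariate[i] == "constant") {
      sprintf("constant [%s]", tm$alternative[i])
    } else {
      sprintf("%s [%s]", tm$covariate[i], tm$alternative[i])
    }
    v[tm$alternative[i]] <- v[tm$alternative[i]] + params[[nm]] * x
  }
  oracle_softmax(v)
}

oracle_mnl_loglik <- function(spec, params, data) {
  ll <- 0
  for (i in seq_len(nrow(data))) {
    p <- oracle_mnl_probs(spec, params, data[i, ])
    ll <- ll + log(p[[as.character(data$outcome[i])]])
  }
  ll
}

# brute-force simulated log-likelihood: per record, per draw, rebuild the
# random coefficient from the draw matrix and average the logit kernel
oracle_simulated_loglik <- function(spec, params, data, draws) {
  n <- nrow(data)
  ll <- 0
  for (i in seq_len(n)) {
    psum <- stats::setNames(numeric(length(spec$alternatives)),
                            spec$alternatives)
    for (kk in seq_len(draws$k)) {
      v <- stats::setNames(numeric(length(spec$alternatives)),
                           spec$alternatives)
      tm <- spec$terms
      for (t in seq_len(nrow(tm))) {
        if (tm$role[t] != "fixed") next
        x <- if (tm$covariate[t] == "constant") 1 else data[[tm$covariate[t]]][i]
        nm <- if (tm$covariate[t] == "constant") {
          sprintf("constant [%s]", tm$alternative[t])
        } else {
          sprintf("%s [%s]", tm$covariate[t], tm$alternative[t])
        }
        v[tm$alternative[t]] <- v[tm$alternative[t]] + params[[nm]] * x
      }
      for (r in seq_len(nrow(spec$random))) {
        rd <- spec$random[r, ]
        lab <- sprintf("%s [%s]", rd$covariate, rd$alternative)
        m <- params[[lab]]
        for (ms in rd$mean_shifters[[1]]) {
          m <- m + params[[sprintf("%s : %s", lab, ms)]] * data[[ms]][i]
        }
        s <- abs(params[[sprintf("sd(%s)", lab)]])
        for (vs in rd$variance_shifters[[1]]) {
          s <- s * exp(params[[sprintf("sd(%s) : %s", lab, vs)]] * data[[vs]][i])
        }
        nu <- draws$values[i, r, kk]
        coef <- if (rd$distribution == "lognormal") {
          rd$sign * exp(m + s * nu)
        } else {
          m + s * nu
        }
        v[rd$alternative] <- v[rd$alternative] + coef * data[[rd$covariate]][i]
      }
      psum <- psum + oracle_softmax(v)
    }
    ll <- ll + log(psum[[as.character(data$outcome[i])]] / draws$k)
  }
  ll
}

# standard-normal quantile by bisection on pnorm: independent of qnorm
oracle_probit <- function(p, tol = 1e-10) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small deterministic three-covariate crash table
toy_crashes <- function(n = 10, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    outcome = factor(sample(severity_levels, n, replace = TRUE),
                     levels = severity_levels),
    male = rbinom(n, 1, 0.7),
    slope = rbinom(n, 1, 0.3),
    rors = rbinom(n, 1, 0.2)
  )
}

toy_mnl_spec <- function() {
  severity_spec() |>
    add_constants() |>
    add_term("male", "minor") |>
    add_term("slope", "severe") |>
    add_term("rors", "fatal")
}

toy_mixed_spec <- function() {
  severity_spec() |>
    add_constants() |>
    add_term("rors", "minor") |>
    add_random_term("male", "minor", mean_shifters = "slope")
}

# a minimal stand-in fit object for tests that only need (spec, estimates,
# draw settings, data)
fake_fit <- function(spec, params, data, k = 60, discard = 100) {
  params <- stats::setNames(as.numeric(params), names(params))
  structure(list(spec = spec, estimates = params, k = k, discard = discard,
                 k_params = n_parameters(spec), data = data),
            class = "mixl_fit")
}
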