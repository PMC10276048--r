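test_that("simulated probabilities reproduce closed forms", {
  d <- toy_crashes()
  spec <- toy_mnl_spec()

  # all parameters zero: equal shares
  p0 <- simulate_probabilities(d, spec, params_template(spec))
  expect_true(all(abs(as.matrix(p0) - 1 / 3) < 1e-15))

  # binary case: fixed utility difference of 1 gives the logistic split
  spec2 <- severity_spec(alternatives = c("minor", "severe")) |>
    add_constants()
  params2 <- c("constant [severe]" = -1)
  p2 <- simulate_probabilities(d, spec2, params2)
  expect_equal(unname(unlist(p2[1, ])), c(1 / (1 + exp(-1)), 1 / (1 + exp(1))),
               tolerance = 1e-10)
  expect_equal(p2$minor[1], 0.73106, tolerance = 1e-5)

  # no random terms: exact MNL probabilities per the independent oracle
  params <- params_template(spec)
  params[] <- c(-0.8, -1.1, 0.5, 0.4, 1.2)
  probs <- simulate_probabilities(d, spec, params)
  for (i in seq_len(nrow(d))) {
    expect_equal(unname(unlist(probs[i, ])),
                 unname(oracle_mnl_probs(spec, params, d[i, ])),
                 tolerance = 1e-12)
  }
})

test_that("probability rows sum to one for arbitrary parameters", {
  d <- toy_crashes(n = 25, seed = 8)
  spec <- toy_mixed_spec()
  for (seed in 1:5) {
    set.seed(seed)
    params <- params_template(spec)
    params[] <- rnorm(length(params), sd = 2)
    probs <- simulate_probabilities(d, spec, params, k = 40)
    expect_true(all(abs(rowSums(as.matrix(probs)) - 1) <= 1e-10))
  }
  # overflow guard: huge utilities stay finite
  big <- params_template(spec)
  big["constant [fatal]"] <- 690
  pb <- simulate_probabilities(d, spec, big, k = 10)
  expect_true(all(is.finite(as.matrix(pb))))
  expect_true(all(pb$fatal > 0.999))
})

test_that("likelihood is invariant to utility shifts common to all alternatives", {
  d <- toy_crashes(n = 15, seed = 4)
  spec <- toy_mnl_spec()
  shifted <- spec |> add_term("male", "severe") |> add_term("male", "fatal")
  params <- params_template(spec)
  params[] <- c(-0.5, -1, 0.7, 0.3, 0.9)
  params_shifted <- params_template(shifted)
  params_shifted[names(params)] <- params
  # the same male coefficient now enters every alternative: pure level shift
  params_shifted["male [severe]"] <- params[["male [minor]"]]
  params_shifted["male [fatal]"] <- params[["male [minor]"]]
  shift <- simulate_probabilities(d, shifted, params_shifted)
  params_nomale <- params; params_nomale["male [minor]"] <- 0
  expect_equal(as.matrix(shift),
               as.matrix(simulate_probabilities(d, spec, params_nomale)),
               tolerance = 1e-12)
  expect_equal(simulated_loglik(d, shifted, params_shifted),
               simulated_loglik(d, spec, params_nomale), tolerance = 1e-12)
})

test_that("simulated log-likelihood matches brute-force recomputation", {
  # uniform probabilities: one observation contributes log(1/3)
  d1 <- toy_crashes(n = 1)
  spec <- toy_mnl_spec()
  expect_equal(simulated_loglik(d1, spec, params_template(spec)), log(1 / 3),
               tolerance = 1e-12)

  # additivity over identical observations
  dN <- d1[rep(1, 7), ]
  params <- params_template(spec)
  params[] <- c(-0.5, -1, 0.7, 0.3, 0.9)
  expect_equal(simulated_loglik(dN, spec, params),
               7 * simulated_loglik(d1, spec, params), tolerance = 1e-10)

  # 10-record fixture with a random coefficient, against the per-record
  # per-draw loop oracle using the same draw matrix
  d <- toy_crashes(n = 10, seed = 21)
  mspec <- severity_spec() |>
    add_constants() |>
    add_term("rors", "minor") |>
    add_random_term("male", "minor", mean_shifters = "slope",
                    variance_shifters = "rors")
  mparams <- params_template(mspec)
  mparams[] <- c(-0.6, -1.0, -1.2, 0.8, -0.9, 1.1, 0.5)
  dm <- make_draw_matrix(10, mspec$random$distribution, k = 25, discard = 15)
  expect_equal(simulated_loglik(d, mspec, mparams, draws = dm),
               oracle_simulated_loglik(mspec, mparams, d, dm),
               tolerance = 1e-10)

  # lognormal random coefficient against the same oracle
  lspec <- severity_spec() |>
    add_constants() |>
    add_random_term("male", "minor", distribution = "lognormal", sign = -1)
  lparams <- params_template(lspec)
  lparams[] <- c(-0.4, -0.9, 0.2, 0.6)
  dml <- make_draw_matrix(10, "lognormal", k = 25, discard = 15)
  expect_equal(simulated_loglik(d, lspec, lparams, draws = dml),
               oracle_simulated_loglik(lspec, lparams, d, dml),
               tolerance = 1e-10)
})

test_that("fit statistics follow their closed forms", {
  expect_equal(null_loglik(773), -849.227, tolerance = 5e-4)
  expect_equal(null_loglik(1228), -1349.096, tolerance = 5e-4)
  expect_equal(null_loglik(1, 2), -log(2))
  expect_equal(null_loglik(1, 2), -0.69315, tolerance = 1e-5)

  expect_equal(round(mcfadden_r2(-849.227, -522.502), 3), 0.385)
  expect_equal(round(mcfadden_r2(-1349.096, -914.609), 3), 0.322)
  expect_equal(mcfadden_r2(-5, -5), 0)

  expect_equal(model_aic(-522.50, 36), 1117.0)
  expect_equal(model_aic(-100, 5), 210)
  expect_true(all(diff(model_aic(-100, 1:10)) > 0))
})

test_that("share of a random coefficient above zero uses the right mass", {
  expect_equal(random_share_split(0.233, 2.082), 0.5446, tolerance = 5e-4)
  expect_equal(random_share_split(1.304, 1.968), 0.7462, tolerance = 5e-4)
  expect_equal(random_share_split(0, 3), 0.5)
  expect_equal(random_share_split(0, 1, "uniform"), 0.5)
  expect_equal(random_share_split(1, 1, "uniform"), 1)
  expect_equal(random_share_split(1, 4, "uniform"), 5 / 8)
  expect_equal(random_share_split(0, 2, "triangular"), 0.5)
  expect_equal(random_share_split(1, 2, "triangular"), 0.875)
  expect_equal(random_share_split(2, 1, "triangular"), 1)
  expect_equal(random_share_split(1, 1, "lognormal"), 1)
  expect_equal(random_share_split(1, 1, "lognormal", sign = -1), 0)
  expect_message(out <- random_share_split(0.5, 0), "degenerate")
  expect_equal(out, 1)
})

test_that("with zero dispersions the simulated likelihood is exactly MNL", {
  d <- toy_crashes(n = 10, seed = 13)
  spec <- toy_mixed_spec()
  params <- params_template(spec)
  params[] <- c(-0.7, -1.1, -1.4, 0.6, 1.2, 0)  # sd(male) = 0
  # MNL spec with the identical systematic utilities, via the loop oracle
  mnl <- severity_spec() |> add_constants() |> add_term("rors", "minor") |>
    add_term("male", "minor") |> add_term("mxs", "minor")
  d_or <- dplyr::mutate(d, mxs = male * slope)
  mnl_params <- c("constant [severe]" = -0.7, "constant [fatal]" = -1.1,
                  "rors [minor]" = -1.4, "male [minor]" = 0.6,
                  "mxs [minor]" = 1.2)
  oracle <- oracle_mnl_loglik(mnl, mnl_params, d_or)
  for (k in c(1, 7, 50)) {
    expect_equal(simulated_loglik(d, spec, params, k = k), oracle,
                 tolerance = 1e-12)
  }
})

test_that("simulated likelihood is stable in the number of draws", {
  truth <- example_truth()
  d <- simulate_crashes(truth, n = 400, seed = 31)
  ll500 <- simulated_loglik(d, truth$spec, truth$params, k = 500)
  ll1000 <- simulated_loglik(d, truth$spec, truth$params, k = 1000)
  expect_lt(abs(ll500 - ll1000) / nrow(d), 0.01)
})

test_that("MNL truth is recovered within 3 standard errors", {
  spec <- toy_mnl_spec()
  truth_params <- params_template(spec)
  truth_params[] <- c(-0.9, -1.4, 0.8, 0.7, 1.1)
  truth <- synthetic_truth(spec, truth_params,
                           c(male = 0.6, slope = 0.3, rors = 0.2))
  d <- simulate_crashes(truth, n = 4000, seed = 17)
  fit <- fit_mixed_logit(d, spec)
  expect_true(fit$converged)
  expect_true(all(abs(fit$estimates - truth_params) < 3 * fit$std_err))
  # LL at the estimate beats the null
  expect_gt(fit$llbeta, fit$ll0)
  expect_equal(glance(fit)$AIC, model_aic(fit$llbeta, 5))
})

test_that("a normal random coefficient and its dispersion are recovered", {
  spec <- severity_spec() |> add_constants() |>
    add_random_term("male", "minor")
  truth_params <- params_template(spec)
  truth_params[] <- c(-0.8, -1.1, 1.0, 1.0)
  truth <- synthetic_truth(spec, truth_params, c(male = 0.5))
  d <- simulate_crashes(truth, n = 2500, seed = 23)
  fit <- fit_mixed_logit(d, spec, k = 150)
  expect_true(fit$converged)
  est <- fit$estimates
  est["sd(male [minor])"] <- abs(est[["sd(male [minor])"]])
  expect_true(all(abs(est - truth_params) < 3 * fit$std_err))
})

test_that("pure-noise outcomes give coefficients near zero", {
  set.seed(41)
  d <- toy_crashes(n = 2000, seed = 19)
  d$outcome <- factor(sample(severity_levels, 2000, replace = TRUE,
                             prob = c(0.7, 0.15, 0.15)),
                      levels = severity_levels)
  fit <- fit_mixed_logit(d, toy_mnl_spec())
  td <- tidy(fit)
  slopes <- td[td$block == "fixed", ]
  expect_true(all(abs(slopes$estimate) < 3 * slopes$std.error))
})

test_that("analytic and finite-difference gradients give the same optimum", {
  truth <- example_truth()
  d <- simulate_crashes(truth, n = 300, seed = 29)
  fa <- fit_mixed_logit(d, truth$spec, k = 40, se = FALSE)
  fn <- fit_mixed_logit(d, truth$spec, k = 40, se = FALSE,
                        gradient = "numeric")
  expect_equal(fa$estimates, fn$estimates, tolerance = 1e-4)
  expect_equal(fa$llbeta, fn$llbeta, tolerance = 1e-8)
})

test_that("non-convergence is reported, never silent", {
  truth <- example_truth()
  d <- simulate_crashes(truth, n = 200, seed = 37)
  fit <- fit_mixed_logit(d, truth$spec, k = 20, se = FALSE,
                         control = list(maxit = 2))
  expect_false(fit$converged)
})

test_that("mixing-distribution comparison prefers the generating distribution", {
  spec <- severity_spec() |> add_constants() |>
    add_random_term("male", "minor")
  truth_params <- params_template(spec)
  truth_params[] <- c(-0.8, -1.1, 1.0, 1.5)
  truth <- synthetic_truth(spec, truth_params, c(male = 0.5))
  d <- simulate_crashes(truth, n = 1200, seed = 43)
  cmp <- compare_mixing_distributions(d, spec, k = 80, se = FALSE)
  expect_equal(nrow(cmp), 4L)
  expect_true(all(cmp$status[is.na(cmp$logLik)] == "fail to converge"))
  ll_normal <- cmp$logLik[cmp$distribution == "normal"]
  others <- cmp$logLik[cmp$distribution != "normal" & cmp$converged]
  expect_true(all(ll_normal >= others - 0.5))

  expect_error(compare_mixing_distributions(d, toy_mnl_spec()), "random")
})
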