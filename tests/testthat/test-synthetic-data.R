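test_that("covariate generation honours frequencies and seeds", {
  freqs <- c(always = 1.0, common = 0.857, rare = 0.05)
  x <- generate_covariates(freqs, n = 1e5, seed = 101)
  expect_true(all(x$always == 1L))
  expect_lt(abs(mean(x$common) - 0.857), 0.005)
  y <- generate_covariates(freqs, n = 1e5, seed = 101)
  expect_identical(x, y)
  z <- generate_covariates(freqs, n = 1e5, seed = 102)
  expect_false(identical(x, z))

  # optional dependence hook induces correlation for the screen to catch
  dep <- list(pairs = list(c("common", "rare")), prob = 0.9)
  w <- generate_covariates(freqs[2:3], n = 5000, seed = 103, dependence = dep)
  expect_gt(cor(w$common, w$rare), 0.5)
})

test_that("outcome simulation follows the utility model", {
  spec <- severity_spec() |> add_constants()
  params <- params_template(spec)
  params["constant [fatal]"] <- 20
  truth <- synthetic_truth(spec, params, c(male = 0.5))
  d <- simulate_crashes(truth, n = 10000, seed = 105)
  expect_gte(mean(d$outcome == "fatal"), 0.999)

  # all parameters zero: shares converge to 1/3
  truth0 <- synthetic_truth(spec, params_template(spec), c(male = 0.5))
  d0 <- simulate_crashes(truth0, n = 30000, seed = 107)
  shares <- as.numeric(table(d0$outcome)) / nrow(d0)
  expect_true(all(abs(shares - 1 / 3) < 0.01))
})

test_that("empirical shares match the truth-implied expected shares", {
  truth <- example_truth()
  n <- 20000
  covs <- generate_covariates(truth, n, seed = 109)
  d <- simulate_outcomes(truth, covs, seed = 110)
  # oracle: per-record expected probabilities by Monte-Carlo integration over
  # the mixing distribution, averaged over records
  set.seed(111)
  reps <- 200
  acc <- matrix(0, n, 3)
  pt <- param_table(truth$spec)
  th <- truth$params
  m_i <- th[["male [minor]"]] + th[["male [minor] : slope"]] * covs$slope
  s_i <- abs(th[["sd(male [minor])"]])
  for (r in seq_len(reps)) {
    coef <- m_i + s_i * rnorm(n)
    v <- cbind(minor = coef * covs$male + th[["rors [minor]"]] * covs$rors,
               severe = rep(th[["constant [severe]"]], n),
               fatal = rep(th[["constant [fatal]"]], n))
    e <- exp(v - apply(v, 1, max))
    acc <- acc + e / rowSums(e)
  }
  expected <- colMeans(acc / reps)
  observed <- as.numeric(table(d$outcome)) / n
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) < 3 * mc_se + 0.003))

  # shares converge with n (small-sample version is noisier but unbiased)
  d_small <- simulate_outcomes(truth,
                               generate_covariates(truth, 1000, seed = 112),
                               seed = 113)
  small_shares <- as.numeric(table(d_small$outcome)) / 1000
  expect_true(all(abs(small_shares - expected) < 0.05))
})

test_that("study-like generation is reproducible with labelled subsets", {
  config <- study_config("distinct")
  study <- generate_study_like(config, seed = 115)
  expect_equal(nrow(study), 6L)
  expect_equal(study$n, purrr::map_int(study$data, nrow))
  expect_setequal(unique(unlist(purrr::map(study$data, "seatbelt"))),
                  seatbelt_levels)
  study2 <- generate_study_like(config, seed = 115)
  expect_identical(study$data, study2$data)

  # shared mode: one truth for all subgroups; distinct mode: truths differ
  shared <- study_config("shared")
  expect_true(all(purrr::map_lgl(shared$truth, function(t) {
    identical(t$params, shared$truth[[1]]$params)
  })))
  expect_false(all(purrr::map_lgl(config$truth, function(t) {
    identical(t$params, config$truth[[1]]$params)
  })))
})

test_that("study data writes CSVs, a dictionary, and the truth", {
  dir <- withr::local_tempdir()
  small <- study_config("shared",
                        n = stats::setNames(rep(30L, 6),
                                            paste(rep(seatbelt_levels, each = 3),
                                                  rep(c("2012-2013", "2014-2015",
                                                        "2016-2017"), 2),
                                                  sep = "|")))
  study <- generate_study_like(small, seed = 117)
  write_study_data(study, dir)
  files <- list.files(dir)
  expect_length(grep("\\.csv$", files), 6L)
  expect_true(all(c("dictionary.yaml", "truth.yaml") %in% files))
  back <- read_crash_table(file.path(dir, "restrained_2012_2013.csv"),
                           dictionary = file.path(dir, "dictionary.yaml"))
  expect_equal(nrow(back), 30L)
  truth_back <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_length(truth_back, 6L)
  expect_equal(truth_back[[1]]$n, 30L)
})
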