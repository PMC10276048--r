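test_that("CSV read-back preserves a toy table and validates covariates", {
  path <- system.file("extdata", "toy_crashes.csv", package = "severomix")
  dict <- system.file("extdata", "toy_dictionary.yaml", package = "severomix")
  d <- read_crash_table(path, dictionary = dict)
  expect_equal(nrow(d), 6L)
  expect_setequal(crash_covariates(d), c("male", "slope", "rors"))
  expect_s3_class(d$outcome, "factor")
  expect_equal(as.integer(d$outcome), c(1L, 2L, 1L, 3L, 1L, 2L))

  # round trip
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_crash_table(d, tmp)
  d2 <- read_crash_table(tmp)
  expect_equal(tibble::as_tibble(d2), tibble::as_tibble(d),
               ignore_attr = TRUE)

  # non-binary covariate value names row and column
  bad <- d
  bad$male[3] <- 2
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(bad, outcome = as.integer(outcome)), tmp2)
  expect_error(read_crash_table(tmp2), "male.*row 3|row 3.*male")

  # missing outcome column
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(d, -"outcome"), tmp3)
  expect_error(read_crash_table(tmp3), "outcome")
})

test_that("subgroup splitting partitions the data", {
  study <- generate_study_like(study_config("shared"), seed = 5)
  pooled <- dplyr::bind_rows(study$data)
  groups <- split_subgroups(pooled)
  expect_equal(nrow(groups), 6L)
  expect_equal(sum(groups$n), nrow(pooled))
  # generator defaults reproduce the six study sample sizes
  sizes <- stats::setNames(groups$n, paste(groups$seatbelt, groups$period,
                                           sep = "|"))
  expect_equal(sizes[["restrained|2012-2013"]], 773L)
  expect_equal(sizes[["unrestrained|2012-2013"]], 1228L)
  expect_equal(sizes[["restrained|2014-2015"]], 999L)
  expect_equal(sizes[["unrestrained|2014-2015"]], 1608L)
  expect_equal(sizes[["restrained|2016-2017"]], 842L)
  expect_equal(sizes[["unrestrained|2016-2017"]], 1387L)

  # single-period input keeps only that period
  one <- split_subgroups(dplyr::filter(pooled, period == "2012-2013"))
  expect_equal(unique(one$period), "2012-2013")
  expect_equal(nrow(one), 2L)

  # missing labels rejected
  expect_error(split_subgroups(dplyr::select(pooled, -seatbelt)), "seatbelt")
})

test_that("descriptive statistics match count arithmetic", {
  d <- tibble::tibble(
    outcome = factor(rep(severity_levels, times = c(583, 108, 82)),
                     levels = severity_levels),
    male = rep(c(1L, 0L), length.out = 773)
  )
  ds <- descriptive_stats(d)
  expect_equal(ds$outcome$count, c(583L, 108L, 82L))
  expect_equal(ds$outcome$percent[1], 75.42)
  expect_lt(abs(sum(ds$outcome$percent) - 100), 0.05)
  # Bernoulli column: sample SD close to sqrt(p(1-p))
  p <- ds$covariates$mean[1]
  expect_equal(ds$covariates$sd[1], sqrt(p * (1 - p)), tolerance = 1e-3)

  all_minor <- tibble::tibble(outcome = factor(rep("minor", 5),
                                               levels = severity_levels))
  expect_equal(descriptive_stats(all_minor)$outcome$percent, c(100, 0, 0))
})

test_that("descriptive percentages sum to 100 for arbitrary data", {
  for (seed in 1:5) {
    d <- toy_crashes(n = 37 + seed, seed = seed)
    expect_lt(abs(sum(descriptive_stats(d)$outcome$percent) - 100), 0.05)
  }
})

test_that("correlation screen flags duplicates and respects the threshold", {
  set.seed(9)
  n <- 10000
  d <- tibble::tibble(
    outcome = factor(rep("minor", n), levels = severity_levels),
    a = rbinom(n, 1, 0.5),
    b = rbinom(n, 1, 0.5)
  )
  d$dup <- d$a
  flagged <- correlation_screen(d)
  expect_equal(nrow(flagged), 1L)
  expect_setequal(c(flagged$var1, flagged$var2), c("a", "dup"))
  expect_equal(flagged$r, 1.0)

  # independent Bernoulli(0.5) pair not flagged at the default 0.7 threshold;
  # flagged correlation agrees with the brute-force Pearson formula
  d2 <- dplyr::select(d, -dup)
  expect_equal(nrow(correlation_screen(d2)), 0L)
  r_brute <- {
    x <- d2$a - mean(d2$a); y <- d2$b - mean(d2$b)
    sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  all_pairs <- correlation_screen(d2, threshold = 1e-12)
  expect_equal(all_pairs$r[1], r_brute, tolerance = 1e-12)
  expect_equal(formals(correlation_screen)$threshold, 0.7)
})

test_that("correlation screen is symmetric and permutation invariant", {
  d <- toy_crashes(n = 60, seed = 2)
  base <- correlation_screen(d, threshold = 0.01)
  resort <- correlation_screen(d[rev(seq_len(nrow(d))), ], threshold = 0.01)
  expect_equal(base, resort, ignore_attr = TRUE)
  swapped <- correlation_screen(
    dplyr::relocate(d, "rors", .after = "outcome"), threshold = 0.01)
  key <- function(t) sort(paste(pmin(t$var1, t$var2), pmax(t$var1, t$var2),
                                round(t$r, 12)))
  expect_equal(key(base), key(swapped))
})

test_that("zero-variance columns are reported separately", {
  d <- toy_crashes(n = 20, seed = 3)
  d$flat <- 0L
  expect_warning(out <- correlation_screen(d), "flat")
  expect_equal(attr(out, "degenerate"), "flat")
})
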