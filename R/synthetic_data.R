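#' Bundle a known truth for synthetic crash data
#'
#' A truth object holds everything the generator needs: the model
#' specification, the true parameter values, and the Bernoulli frequency of
#' each covariate.  Crash datasets simulated from a truth follow exactly the
#' data-generating process the estimator assumes (random coefficients built
#' from the mean/variance-shifter structure, logit outcome kernel), so a fit
#' of the generating spec to a large sample must recover the parameters.
#'
#' @param spec A [severity_spec()].
#' @param params Named parameter vector (see [param_table()]); unnamed values
#'   are matched by position.
#' @param covariate_frequencies Named vector of Bernoulli probabilities, one
#'   per covariate used by the spec.
#' @return Object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(spec, params, covariate_frequencies) {
  params <- check_params(params, spec)
  stopifnot(all(covariate_frequencies >= 0), all(covariate_frequencies <= 1))
  missing <- setdiff(spec_covariates(spec), names(covariate_frequencies))
  if (length(missing) > 0L) {
    stop("no frequency for covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(spec = spec, params = params,
                 covariate_frequencies = covariate_frequencies),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", n_parameters(x$spec), "parameters,",
      length(x$covariate_frequencies), "covariates\n")
  print(round(x$params, 3))
  invisible(x)
}

#' A small example truth
#'
#' Constants for severe and fatal, one fixed coefficient (run-off-road on a
#' straight, lowering minor-injury utility), and a random male-driver
#' coefficient on the minor-injury utility whose mean is shifted by the
#' sloped-road indicator.  Round-number parameter values with the sign
#' pattern typical of severity models; covariate frequencies match commonly
#' observed crash-data shares (male 0.857, slope 0.107, run-off-straight
#' 0.111).
#'
#' @return A [synthetic_truth()].
#' @export
example_truth <- function() {
  spec <- severity_spec() |>
    add_constants() |>
    add_term("rors", "minor") |>
    add_random_term("male", "minor", distribution = "normal",
                    mean_shifters = "slope")
  params <- params_template(spec)
  params["constant [severe]"] <- -1.0
  params["constant [fatal]"] <- -1.3
  params["rors [minor]"] <- -1.5
  params["male [minor]"] <- 0.25
  params["male [minor] : slope"] <- 1.5
  params["sd(male [minor])"] <- 2.0
  synthetic_truth(spec, params,
                  c(male = 0.857, slope = 0.107, rors = 0.111))
}

#' Generate Bernoulli covariates
#'
#' Independent Bernoulli draws per covariate at the truth's stated
#' frequencies.  An optional shared latent Bernoulli mixing component can
#' induce pairwise dependence between covariates, to exercise the
#' multicollinearity screen; by default covariates are independent.
#'
#' @param truth A [synthetic_truth()], or a named frequency vector.
#' @param n Number of records.
#' @param seed RNG seed (required for reproducibility).
#' @param dependence Optional list `list(pairs = list(c("a", "b")), prob =
#'   0.5)`: for each pair, with probability `prob` a record copies the first
#'   covariate's value into the second, inducing positive correlation.
#' @return Tibble of 0/1 covariate columns.
#' @export
generate_covariates <- function(truth, n, seed, dependence = NULL) {
  freqs <- if (inherits(truth, "synthetic_truth")) {
    truth$covariate_frequencies
  } else {
    truth
  }
  stopifnot(n >= 1)
  set.seed(seed)
  out <- tibble::as_tibble(purrr::map(freqs, function(p) {
    stats::rbinom(n, 1L, p)
  }))
  if (!is.null(dependence)) {
    for (pair in dependence$pairs) {
      copy <- stats::rbinom(n, 1L, dependence$prob %||% 0.5) == 1L
      out[[pair[2]]][copy] <- out[[pair[1]]][copy]
    }
  }
  out
}

#' Simulate severity outcomes from a truth
#'
#' Per record: draw one realisation of each random coefficient from its
#' mixing distribution (mean and scale built from the record's own shifter
#' values), form the three utilities, convert to closed-form logit
#' probabilities at the realised coefficients — equivalent to adding
#' independent Gumbel errors to the utilities — and sample the outcome
#' multinomially.
#'
#' @param truth A [synthetic_truth()].
#' @param covariates Tibble of 0/1 covariates covering the spec.
#' @param seed RNG seed.
#' @return A crash tibble: `outcome` plus the covariate columns.
#' @export
simulate_outcomes <- function(truth, covariates, seed) {
  set.seed(seed)
  spec <- truth$spec
  theta <- truth$params
  n <- nrow(covariates)
  X <- cbind(constant = rep(1, n), as.matrix(covariates))
  pt <- param_table(spec)
  pidx <- stats::setNames(seq_len(nrow(pt)), pt$name)
  v <- matrix(0, n, length(spec$alternatives))
  fx <- pt[pt$block %in% c("constant", "fixed"), , drop = FALSE]
  for (i in seq_len(nrow(fx))) {
    a <- match(fx$alternative[i], spec$alternatives)
    v[, a] <- v[, a] + theta[pidx[[fx$name[i]]]] * X[, fx$covariate[i]]
  }
  for (r in seq_len(nrow(spec$random))) {
    rd <- spec$random[r, ]
    lab <- sprintf("%s [%s]", rd$covariate, rd$alternative)
    ms <- rd$mean_shifters[[1]]; vs <- rd$variance_shifters[[1]]
    m_i <- theta[pidx[[lab]]] +
      if (length(ms)) {
        drop(X[, ms, drop = FALSE] %*%
               theta[pidx[sprintf("%s : %s", lab, ms)]])
      } else 0
    s_i <- abs(theta[pidx[[sprintf("sd(%s)", lab)]]]) *
      if (length(vs)) {
        exp(drop(X[, vs, drop = FALSE] %*%
                   theta[pidx[sprintf("sd(%s) : %s", lab, vs)]]))
      } else 1
    nu <- switch(rd$distribution,
      normal = stats::rnorm(n),
      lognormal = stats::rnorm(n),
      uniform = stats::runif(n, -1, 1),
      triangular = standard_triangular(stats::runif(n))
    )
    coef <- if (rd$distribution == "lognormal") {
      rd$sign * exp(m_i + s_i * nu)
    } else {
      m_i + s_i * nu
    }
    a <- match(rd$alternative, spec$alternatives)
    v[, a] <- v[, a] + X[, rd$covariate] * coef
  }
  ev <- exp(v - apply(v, 1, max))
  p <- ev / rowSums(ev)
  u <- stats::runif(n)
  cum <- t(apply(p, 1, cumsum))
  idx <- 1L + as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
  out <- tibble::as_tibble(covariates)
  out <- dplyr::mutate(out,
    outcome = factor(spec$alternatives[idx], levels = spec$alternatives),
    .before = 1)
  out
}

#' Convenience: generate covariates and outcomes in one call
#'
#' @param truth A [synthetic_truth()].
#' @param n Number of records.
#' @param seed RNG seed (covariates use `seed`, outcomes `seed + 1`).
#' @param seatbelt,period Optional labels attached to every record.
#' @param dependence Passed to [generate_covariates()].
#' @return A crash tibble.
#' @export
simulate_crashes <- function(truth, n, seed, seatbelt = NULL, period = NULL,
                             dependence = NULL) {
  covs <- generate_covariates(truth, n, seed, dependence = dependence)
  data <- simulate_outcomes(truth, covs, seed + 1L)
  if (!is.null(seatbelt)) {
    data <- dplyr::mutate(data, seatbelt = seatbelt, .after = "outcome")
  }
  if (!is.null(period)) {
    data <- dplyr::mutate(data, period = period, .after = "outcome")
  }
  data
}

#' Configuration for a study-like six-subgroup dataset
#'
#' Two seatbelt states crossed with three biennial periods.  Default subgroup
#' sizes are the study's: restrained 773 / 999 / 842 and unrestrained
#' 1228 / 1608 / 1387 across 2012-2013, 2014-2015, 2016-2017.  The shared
#' spec has constants, three fixed coefficients and one random four-lane
#' coefficient on the minor-injury utility with an old-driver mean shifter;
#' covariate frequencies follow the observed crash-data shares.
#'
#' In `"distinct"` mode each subgroup gets its own parameter values,
#' separated by gaps of 0.6-1.2 in the constants and fixed coefficients (so
#' transferability tests should reject); in `"shared"` mode all six subgroups
#' share one truth (so the tests should reject only at their nominal size).
#'
#' @param mode `"distinct"` or `"shared"`.
#' @param n Named integer vector of subgroup sizes; names
#'   `"<seatbelt>|<period>"`.
#' @return A tibble with columns `seatbelt`, `period`, `n`, `truth`
#'   (list-column of [synthetic_truth()]).
#' @export
study_config <- function(mode = c("distinct", "shared"), n = NULL) {
  mode <- match.arg(mode)
  periods <- c("2012-2013", "2014-2015", "2016-2017")
  default_n <- c("restrained|2012-2013" = 773L,
                 "restrained|2014-2015" = 999L,
                 "restrained|2016-2017" = 842L,
                 "unrestrained|2012-2013" = 1228L,
                 "unrestrained|2014-2015" = 1608L,
                 "unrestrained|2016-2017" = 1387L)
  if (is.null(n)) n <- default_n
  spec <- severity_spec() |>
    add_constants() |>
    add_term("rors", "minor") |>
    add_term("flush_median", "fatal") |>
    add_term("slope", "severe") |>
    add_random_term("four_lane", "minor", distribution = "normal",
                    mean_shifters = "old")
  freqs <- c(four_lane = 0.645, old = 0.165, rors = 0.111,
             flush_median = 0.046, slope = 0.107)
  base_params <- params_template(spec)
  base_params["constant [severe]"] <- -1.2
  base_params["constant [fatal]"] <- -1.3
  base_params["rors [minor]"] <- -1.5
  base_params["flush_median [fatal]"] <- 1.5
  base_params["slope [severe]"] <- 0.7
  base_params["four_lane [minor]"] <- 1.3
  base_params["four_lane [minor] : old"] <- -1.2
  base_params["sd(four_lane [minor])"] <- 2.0

  grid <- expand.grid(seatbelt = seatbelt_levels, period = periods,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$seatbelt, grid$period), , drop = FALSE]
  truths <- purrr::map(seq_len(nrow(grid)), function(i) {
    params <- base_params
    if (mode == "distinct") {
      # systematic, sizeable gaps: every subgroup pair differs by >= 0.3 in
      # the constants and four-lane mean and by 1.6 in the rors coefficient
      # between seatbelt groups
      delta <- seq(-0.75, 0.75, by = 0.3)[i]
      params["constant [severe]"] <- base_params["constant [severe]"] + delta
      params["constant [fatal]"] <- base_params["constant [fatal]"] - delta
      params["rors [minor]"] <- base_params["rors [minor]"] +
        if (i %% 2 == 0) 0.8 else -0.8
      params["four_lane [minor]"] <- base_params["four_lane [minor]"] + delta
    }
    synthetic_truth(spec, params, freqs)
  })
  tibble::tibble(
    seatbelt = grid$seatbelt, period = grid$period,
    n = unname(n[paste(grid$seatbelt, grid$period, sep = "|")]),
    truth = truths
  )
}

#' Generate a study-like six-subgroup crash dataset
#'
#' Simulates each subgroup of `config` with its own truth and labels the
#' records with seatbelt status and period.  Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [study_config()] tibble (or one with edited sizes /
#'   truths).
#' @param seed Base RNG seed; subgroup `i` uses `seed + 10 * i`.
#' @return The `config` tibble with a `data` list-column of crash tibbles.
#'   `dplyr::bind_rows(out$data)` gives the pooled dataset.
#' @export
generate_study_like <- function(config = study_config(), seed = 1) {
  config$data <- purrr::map(seq_len(nrow(config)), function(i) {
    simulate_crashes(config$truth[[i]], config$n[i], seed + 10L * i,
                     seatbelt = config$seatbelt[i], period = config$period[i])
  })
  config
}

#' Write a generated study to disk
#'
#' One CSV per subgroup plus a YAML variable dictionary and a YAML file of
#' the true (synthetic) parameter values, the layout consumed by
#' [read_crash_table()].
#'
#' @param study Output of [generate_study_like()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_data <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(study))) {
    stem <- paste0(study$seatbelt[i], "_", gsub("[^0-9]", "_",
                                                study$period[i]))
    write_crash_table(study$data[[i]], file.path(dir, paste0(stem, ".csv")))
  }
  freqs <- study$truth[[1]]$covariate_frequencies
  dictionary <- list(
    outcome = "outcome", seatbelt = "seatbelt", period = "period",
    covariates = as.list(stats::setNames(
      paste0("synthetic Bernoulli(", freqs, ") indicator"), names(freqs)))
  )
  yaml::write_yaml(dictionary, file.path(dir, "dictionary.yaml"))
  truths <- purrr::map(seq_len(nrow(study)), function(i) {
    list(seatbelt = study$seatbelt[i], period = study$period[i],
         n = study$n[i], params = as.list(study$truth[[i]]$params))
  })
  yaml::write_yaml(truths, file.path(dir, "truth.yaml"))
  invisible(dir)
}
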