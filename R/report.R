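#' Publication-style estimation report
#'
#' Aligned-text rendering of a fitted model in the conventional layout:
#' coefficients with t-statistics, grouped heterogeneity-in-means and
#' heterogeneity-in-variances blocks, then model statistics (observations,
#' LL(0), LL(beta), McFadden pseudo R-squared, AIC).  Parameters significant
#' at the two-sided 0.1 level are starred, the usual reporting convention for
#' these models.
#'
#' @param fit A [fit_mixed_logit()] object.
#' @param sig_level Two-sided significance level for the star (default 0.1).
#' @return Character vector of report lines.
#' @export
fit_report <- function(fit, sig_level = 0.1) {
  td <- tidy(fit)
  fmt_row <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      star <- if (!is.na(rows$p.value[i]) && rows$p.value[i] <= sig_level) {
        "*"
      } else {
        " "
      }
      sprintf("  %-36s %9.3f  %7.2f%s", rows$term[i], rows$estimate[i],
              rows$statistic[i], star)
    }, character(1))
  }
  main <- td[td$block %in% c("constant", "fixed", "rand_mean", "rand_sd"), ]
  het_m <- td[td$block == "het_mean", ]
  het_s <- td[td$block == "het_sd", ]
  g <- glance(fit)
  lines <- c(
    "Mixed logit severity model (simulated maximum likelihood)",
    sprintf("  %-36s %9s  %8s", "Variable", "Coef.", "t-Stat"),
    fmt_row(main)
  )
  if (nrow(het_m) > 0) lines <- c(lines, "Heterogeneity in means:",
                                  fmt_row(het_m))
  if (nrow(het_s) > 0) lines <- c(lines, "Heterogeneity in variances:",
                                  fmt_row(het_s))
  c(lines,
    "Model statistics:",
    sprintf("  Number of observations   %d", g$nobs),
    sprintf("  Number of parameters     %d", g$k),
    sprintf("  Halton draws             %d", g$draws),
    sprintf("  LL(0)                    %.3f", g$null.logLik),
    sprintf("  LL(beta)                 %.3f", g$logLik),
    sprintf("  McFadden Pseudo R^2      %.3f", g$mcfadden.r2),
    sprintf("  AIC                      %.2f", g$AIC),
    if (!g$converged) "  WARNING: optimiser did not converge" else NULL)
}

#' Random-parameter discovery helper
#'
#' The conventional specification loop: starting from a fixed-coefficient
#' model, each candidate term is allowed to vary (one at a time) and kept
#' random only if the t-statistic of its standard deviation is significant.
#' Offered as an explicit helper — it is never run implicitly.
#'
#' @param data Crash tibble.
#' @param spec A fixed-coefficient [severity_spec()].
#' @param candidates Tibble / data frame with columns `covariate`,
#'   `alternative`: terms of `spec` to test as random.
#' @param distribution Mixing distribution for the candidates.
#' @param sig_level Significance level for keeping a random term.
#' @param ... Passed to [fit_mixed_logit()].
#' @return Tibble: `covariate`, `alternative`, `sd_estimate`, `sd_t_stat`,
#'   `keep_random`.
#' @export
test_random_candidates <- function(data, spec, candidates,
                                   distribution = "normal", sig_level = 0.1,
                                   ...) {
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cv <- candidates$covariate[i]; alt <- candidates$alternative[i]
    sp <- spec
    keep <- sp$terms$covariate == cv & sp$terms$alternative == alt
    sp$terms <- sp$terms[!keep, , drop = FALSE]
    sp <- add_random_term(sp, cv, alt, distribution = distribution)
    fit <- tryCatch(fit_mixed_logit(data, sp, ...), error = function(e) NULL)
    nm <- sprintf("sd(%s [%s])", cv, alt)
    tibble::tibble(
      covariate = cv, alternative = alt,
      sd_estimate = if (is.null(fit)) NA_real_ else abs(fit$estimates[[nm]]),
      sd_t_stat = if (is.null(fit)) NA_real_ else fit$t_stat[[nm]],
      keep_random = !is.null(fit) && !is.na(fit$p_value[[nm]]) &&
        fit$p_value[[nm]] <= sig_level
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full six-subgroup severity analysis
#'
#' Fits one model per subgroup, then produces descriptive statistics, the
#' marginal-effects tables, the two likelihood-ratio matrices
#' (restrained-vs-unrestrained transferability within each period; pairwise
#' temporal instability within each seatbelt group), and the out-of-sample
#' prediction comparisons (restrained model forecasting unrestrained data per
#' period; earlier-period models forecasting later periods per seatbelt
#' group).  Optionally writes every table as CSV plus a manifest for
#' reproducibility.
#'
#' @param study A [generate_study_like()] tibble, or any tibble with columns
#'   `seatbelt`, `period`, `data` (list of crash tibbles).
#' @param spec A [severity_spec()] used for all subgroups, or a list of specs
#'   named `"<seatbelt>|<period>"`.
#' @param k,discard Draw settings for estimation.
#' @param out_dir Optional output directory for CSV tables and a
#'   `manifest.yaml` (config, package version, seed) sufficient to reproduce
#'   the outputs.
#' @param seed Recorded in the manifest (the analysis itself is deterministic
#'   given the data and draw settings).
#' @param ... Passed to [fit_mixed_logit()].
#' @return List with elements `fits`, `descriptives`, `effects`,
#'   `transferability`, `temporal`, `predictions`, `temporal_predictions`.
#' @export
run_severity_study <- function(study, spec, k = 250, discard = 100,
                               out_dir = NULL, seed = NULL, ...) {
  key <- paste(study$seatbelt, study$period, sep = "|")
  datasets <- stats::setNames(study$data, key)
  fits <- purrr::imap(datasets, function(d, nm) {
    sp <- if (inherits(spec, "severity_spec")) spec else spec[[nm]]
    fit_mixed_logit(d, sp, k = k, discard = discard, ...)
  })
  descriptives <- purrr::map(datasets, descriptive_stats)
  effects <- purrr::imap(fits, function(f, nm) marginal_effects_table(f))

  periods <- sort(unique(study$period))
  transfer_pairs <- dplyr::bind_rows(purrr::map(periods, function(p) {
    tibble::tibble(
      model = paste0(c("restrained|", "unrestrained|"), p),
      data = paste0(c("unrestrained|", "restrained|"), p)
    )
  }))
  transferability <- lr_test_matrix(fits, datasets, pairs = transfer_pairs)

  temporal <- dplyr::bind_rows(purrr::map(seatbelt_levels, function(sb) {
    keys <- paste(sb, periods, sep = "|")
    pairs <- expand.grid(model = keys, data = keys, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$model != pairs$data, , drop = FALSE]
    lr_test_matrix(fits, datasets, pairs = pairs)
  }))

  predictions <- dplyr::bind_rows(purrr::map(periods, function(p) {
    cmp <- compare_predictions(fits[[paste0("restrained|", p)]],
                               fits[[paste0("unrestrained|", p)]])
    dplyr::bind_cols(tibble::tibble(period = p), cmp)
  }))
  temporal_predictions <- dplyr::bind_rows(
    purrr::map(seatbelt_levels, function(sb) {
      keys <- paste(sb, periods, sep = "|")
      out <- temporal_forecast_matrix(
        stats::setNames(fits[keys], periods),
        stats::setNames(datasets[keys], periods))
      dplyr::bind_cols(tibble::tibble(seatbelt = sb), out)
    }))

  result <- list(fits = fits, descriptives = descriptives, effects = effects,
                 transferability = transferability, temporal = temporal,
                 predictions = predictions,
                 temporal_predictions = temporal_predictions)
  if (!is.null(out_dir)) {
    write_study_tables(result, out_dir, k = k, discard = discard, seed = seed)
  }
  result
}

write_study_tables <- function(result, out_dir, k, discard, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coef_tables <- dplyr::bind_rows(purrr::imap(result$fits, function(f, nm) {
    dplyr::bind_cols(tibble::tibble(subgroup = nm), tidy(f))
  }))
  readr::write_csv(coef_tables, file.path(out_dir, "coefficients.csv"))
  fitstats <- dplyr::bind_rows(purrr::imap(result$fits, function(f, nm) {
    dplyr::bind_cols(tibble::tibble(subgroup = nm), glance(f))
  }))
  readr::write_csv(fitstats, file.path(out_dir, "fit_statistics.csv"))
  eff <- dplyr::bind_rows(purrr::imap(result$effects, function(e, nm) {
    dplyr::bind_cols(tibble::tibble(subgroup = nm), tibble::as_tibble(e))
  }))
  readr::write_csv(eff, file.path(out_dir, "marginal_effects.csv"))
  desc <- dplyr::bind_rows(purrr::imap(result$descriptives, function(ds, nm) {
    dplyr::bind_cols(tibble::tibble(subgroup = nm), ds$outcome)
  }))
  readr::write_csv(desc, file.path(out_dir, "descriptives.csv"))
  readr::write_csv(dplyr::select(result$transferability, -"refit"),
                   file.path(out_dir, "transferability.csv"))
  readr::write_csv(dplyr::select(result$temporal, -"refit"),
                   file.path(out_dir, "temporal_stability.csv"))
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  readr::write_csv(result$temporal_predictions,
                   file.path(out_dir, "temporal_predictions.csv"))
  manifest <- list(
    package = "severomix",
    version = as.character(utils::packageVersion("severomix")),
    draws = k, discard = discard, seed = seed,
    created = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
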