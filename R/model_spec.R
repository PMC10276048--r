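#' Create a severity model specification
#'
#' A specification lists, per severity level, which covariates enter that
#' level's utility function, which of those coefficients are random (with a
#' named mixing distribution), and which covariates shift the mean and the
#' (log-)standard deviation of each random coefficient.  One severity level
#' is the base alternative: its utility carries no constant, fixing the scale
#' for identification.
#'
#' Build a specification with the pipe:
#' `severity_spec() |> add_constants() |> add_term("rors", "minor") |>
#'  add_random_term("male", "minor", mean_shifters = "slope")`.
#'
#' @param alternatives Ordered severity levels (default [severity_levels]).
#' @param base Base alternative whose constant is fixed at zero; defaults to
#'   `"minor"`, so constants are estimated for severe and fatal only.
#' @return An object of class `"severity_spec"`.
#' @seealso [add_constants()], [add_term()], [add_random_term()],
#'   [validate_spec()], [spec_from_config()]
#' @export
severity_spec <- function(alternatives = severity_levels,
                          base = alternatives[1]) {
  stopifnot(length(alternatives) >= 2, !anyDuplicated(alternatives))
  if (!base %in% alternatives) stop("base alternative '", base,
                                    "' not among alternatives", call. = FALSE)
  structure(
    list(
      alternatives = alternatives,
      base = base,
      terms = tibble::tibble(covariate = character(), alternative = character(),
                             role = character()),
      random = tibble::tibble(covariate = character(), alternative = character(),
                              distribution = character(), sign = numeric(),
                              mean_shifters = list(), variance_shifters = list())
    ),
    class = "severity_spec"
  )
}

.mixing_distributions <- c("normal", "triangular", "uniform", "lognormal")

check_term_free <- function(spec, covariate, alternative) {
  if (!alternative %in% spec$alternatives) {
    stop("unknown alternative '", alternative, "'", call. = FALSE)
  }
  dup <- spec$terms$covariate == covariate &
    spec$terms$alternative == alternative
  if (any(dup)) {
    stop("term (", covariate, ", ", alternative, ") already in spec",
         call. = FALSE)
  }
}

#' Add alternative-specific constants
#'
#' @param spec A [severity_spec()].
#' @param alternatives Levels receiving a constant; defaults to every non-base
#'   alternative.  Adding a constant on the base alternative is an
#'   identification error caught by [validate_spec()].
#' @return The updated spec.
#' @export
add_constants <- function(spec, alternatives = setdiff(spec$alternatives,
                                                       spec$base)) {
  for (alt in alternatives) spec <- add_term(spec, "constant", alt)
  spec
}

#' Add a fixed-coefficient utility term
#'
#' @param spec A [severity_spec()].
#' @param covariate Covariate name, or `"constant"`.
#' @param alternative Severity level whose utility the term enters.  A
#'   covariate entering several alternatives needs one term per alternative.
#' @return The updated spec.
#' @export
add_term <- function(spec, covariate, alternative) {
  check_term_free(spec, covariate, alternative)
  spec$terms <- dplyr::bind_rows(
    spec$terms,
    tibble::tibble(covariate = covariate, alternative = alternative,
                   role = "fixed")
  )
  spec
}

#' Add a random-coefficient utility term
#'
#' The coefficient of `covariate` in `alternative`'s utility varies across
#' crashes: its mean is shifted linearly by the `mean_shifters` covariates and
#' its standard deviation is scaled by `exp(omega' SD_i)` over the
#' `variance_shifters` covariates, around a baseline dispersion estimated from
#' the data.
#'
#' @param spec A [severity_spec()].
#' @param covariate,alternative As in [add_term()].
#' @param distribution Mixing distribution: `"normal"`, `"triangular"`,
#'   `"uniform"` (both parameterised by mean and spread, symmetric about the
#'   mean) or `"lognormal"` (coefficient `sign * exp(location + scale * nu)`,
#'   sign-definite).
#' @param mean_shifters,variance_shifters Covariate names shifting the mean /
#'   the log standard deviation; must differ from `covariate` itself.
#' @param sign For `"lognormal"` only: `+1` or `-1`, the sign of the
#'   coefficient.
#' @return The updated spec.
#' @export
add_random_term <- function(spec, covariate, alternative,
                            distribution = "normal",
                            mean_shifters = character(),
                            variance_shifters = character(),
                            sign = 1) {
  check_term_free(spec, covariate, alternative)
  distribution <- match.arg(distribution, .mixing_distributions)
  stopifnot(sign %in% c(-1, 1))
  if (covariate %in% c(mean_shifters, variance_shifters)) {
    stop("shifters must differ from the random covariate itself", call. = FALSE)
  }
  spec$terms <- dplyr::bind_rows(
    spec$terms,
    tibble::tibble(covariate = covariate, alternative = alternative,
                   role = "random")
  )
  spec$random <- dplyr::bind_rows(
    spec$random,
    tibble::tibble(covariate = covariate, alternative = alternative,
                   distribution = distribution, sign = sign,
                   mean_shifters = list(mean_shifters),
                   variance_shifters = list(variance_shifters))
  )
  spec
}

#' Number of estimable parameters of a specification
#'
#' Counts constants, fixed coefficients, random-coefficient means, baseline
#' dispersions, heterogeneity-in-mean coefficients and heterogeneity-in-
#' variance coefficients.  Invariant under term reordering.
#'
#' @param spec A [severity_spec()].
#' @return Integer parameter count `k`.
#' @export
n_parameters <- function(spec) {
  nrow(param_table(spec))
}

#' Parameter table of a specification
#'
#' One row per estimable parameter, in reporting order: constants, fixed
#' coefficients, then per random term its mean, heterogeneity-in-mean
#' coefficients, dispersion, and heterogeneity-in-variance coefficients.
#' Names follow the field's table conventions, e.g. `"male [minor]"`,
#' `"sd(male [minor])"`, `"male [minor] : slope"`.
#'
#' @param spec A [severity_spec()].
#' @return Tibble with columns `name`, `block` (`constant`, `fixed`,
#'   `rand_mean`, `het_mean`, `rand_sd`, `het_sd`), `covariate`,
#'   `alternative`, `rand_id`, `shifter`.
#' @export
param_table <- function(spec) {
  rows <- list()
  add <- function(name, block, covariate, alternative, rand_id = NA_integer_,
                  shifter = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, block = block, covariate = covariate,
      alternative = alternative, rand_id = rand_id, shifter = shifter)
  }
  fixed <- spec$terms[spec$terms$role == "fixed", , drop = FALSE]
  for (i in seq_len(nrow(fixed))) {
    cv <- fixed$covariate[i]; alt <- fixed$alternative[i]
    if (cv == "constant") {
      add(sprintf("constant [%s]", alt), "constant", cv, alt)
    }
  }
  for (i in seq_len(nrow(fixed))) {
    cv <- fixed$covariate[i]; alt <- fixed$alternative[i]
    if (cv != "constant") {
      add(sprintf("%s [%s]", cv, alt), "fixed", cv, alt)
    }
  }
  for (r in seq_len(nrow(spec$random))) {
    cv <- spec$random$covariate[r]; alt <- spec$random$alternative[r]
    lab <- sprintf("%s [%s]", cv, alt)
    add(lab, "rand_mean", cv, alt, rand_id = r)
    for (m in spec$random$mean_shifters[[r]]) {
      add(sprintf("%s : %s", lab, m), "het_mean", cv, alt, rand_id = r,
          shifter = m)
    }
    add(sprintf("sd(%s)", lab), "rand_sd", cv, alt, rand_id = r)
    for (s in spec$random$variance_shifters[[r]]) {
      add(sprintf("sd(%s) : %s", lab, s), "het_sd", cv, alt, rand_id = r,
          shifter = s)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(name = character(), block = character(),
                          covariate = character(), alternative = character(),
                          rand_id = integer(), shifter = character()))
  }
  dplyr::bind_rows(rows)
}

#' Covariates referenced anywhere in a specification
#' @param spec A [severity_spec()].
#' @return Character vector of covariate names (excluding `"constant"`).
#' @export
spec_covariates <- function(spec) {
  shifters <- unlist(c(spec$random$mean_shifters, spec$random$variance_shifters))
  unique(setdiff(c(spec$terms$covariate, shifters), "constant"))
}

#' Validate a specification against a crash table
#'
#' Collects all problems (unresolved covariates, constants on the base
#' alternative, shifters on non-existent terms) into a report rather than
#' stopping at the first, so they can be printed together.
#'
#' @param spec A [severity_spec()].
#' @param data Optional crash tibble to resolve covariates against.
#' @return A list of class `"spec_validation"` with elements `ok` (logical),
#'   `errors` (character vector) and `k` (parameter count).
#' @export
validate_spec <- function(spec, data = NULL) {
  errors <- character()
  base_const <- spec$terms$covariate == "constant" &
    spec$terms$alternative == spec$base
  if (any(base_const)) {
    errors <- c(errors, paste0(
      "constant on base alternative '", spec$base,
      "' is not identified (one constant must be fixed at zero)"))
  }
  if (!any(spec$terms$covariate == "constant")) {
    errors <- c(errors, "no alternative-specific constants in spec")
  }
  bad_alt <- setdiff(spec$terms$alternative, spec$alternatives)
  if (length(bad_alt) > 0L) {
    errors <- c(errors, paste0("unknown alternative(s): ",
                               paste(bad_alt, collapse = ", ")))
  }
  if (!is.null(data)) {
    missing <- setdiff(spec_covariates(spec), names(data))
    if (length(missing) > 0L) {
      errors <- c(errors, paste0("covariate(s) not in data: ",
                                 paste(missing, collapse = ", ")))
    }
  }
  structure(list(ok = length(errors) == 0L, errors = errors,
                 k = n_parameters(spec)),
            class = "spec_validation")
}

#' @export
print.spec_validation <- function(x, ...) {
  if (x$ok) {
    cat("Specification OK;", x$k, "estimable parameters.\n")
  } else {
    cat("Specification problems:\n")
    for (e in x$errors) cat("  -", e, "\n")
  }
  invisible(x)
}

#' @export
print.severity_spec <- function(x, ...) {
  cat("Severity model specification\n")
  cat("  alternatives:", paste(x$alternatives, collapse = " < "),
      " (base:", x$base, ")\n")
  pt <- param_table(x)
  cat("  parameters (k =", nrow(pt), "):\n")
  for (nm in pt$name) cat("    ", nm, "\n", sep = "")
  invisible(x)
}

#' Read a model specification from a YAML config
#'
#' The config schema:
#' ```yaml
#' alternatives: [minor, severe, fatal]
#' base: minor
#' constants: [severe, fatal]
#' terms:
#'   - {covariate: rors, alternative: minor}
#' random:
#'   - covariate: male
#'     alternative: minor
#'     distribution: normal
#'     mean_shifters: [slope]
#'     variance_shifters: []
#'     sign: 1
#' ```
#' `spec_from_config(spec_to_config(spec))` is the identity.
#'
#' @param config A YAML file path or an already-parsed list.
#' @return A [severity_spec()].
#' @export
spec_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  spec <- severity_spec(
    alternatives = config$alternatives %||% severity_levels,
    base = config$base %||% (config$alternatives %||% severity_levels)[1]
  )
  for (alt in config$constants %||% character()) {
    spec <- add_term(spec, "constant", alt)
  }
  for (tm in config$terms %||% list()) {
    spec <- add_term(spec, tm$covariate, tm$alternative)
  }
  for (rd in config$random %||% list()) {
    if (!is.null(rd$distribution) &&
        !rd$distribution %in% .mixing_distributions) {
      stop("unknown distribution '", rd$distribution, "'", call. = FALSE)
    }
    spec <- add_random_term(
      spec, rd$covariate, rd$alternative,
      distribution = rd$distribution %||% "normal",
      mean_shifters = unlist(rd$mean_shifters) %||% character(),
      variance_shifters = unlist(rd$variance_shifters) %||% character(),
      sign = rd$sign %||% 1
    )
  }
  spec
}

#' Serialise a model specification to a config list (or YAML file)
#'
#' @param spec A [severity_spec()].
#' @param path Optional path; if given the YAML is written there.
#' @return The config as a list, invisibly if `path` is given.
#' @export
spec_to_config <- function(spec, path = NULL) {
  fixed <- spec$terms[spec$terms$role == "fixed", , drop = FALSE]
  consts <- fixed$alternative[fixed$covariate == "constant"]
  terms <- fixed[fixed$covariate != "constant", , drop = FALSE]
  config <- list(
    alternatives = spec$alternatives,
    base = spec$base,
    constants = as.list(consts),
    terms = purrr::map(seq_len(nrow(terms)), function(i) {
      list(covariate = terms$covariate[i], alternative = terms$alternative[i])
    }),
    random = purrr::map(seq_len(nrow(spec$random)), function(r) {
      list(covariate = spec$random$covariate[r],
           alternative = spec$random$alternative[r],
           distribution = spec$random$distribution[r],
           mean_shifters = as.list(spec$random$mean_shifters[[r]]),
           variance_shifters = as.list(spec$random$variance_shifters[[r]]),
           sign = spec$random$sign[r])
    })
  )
  if (!is.null(path)) {
    yaml::write_yaml(config, path)
    return(invisible(config))
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
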