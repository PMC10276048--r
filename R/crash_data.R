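#' @importFrom rlang .data :=
NULL

#' Severity levels used throughout the package
#'
#' Three-level driver injury severity as coded by highway police: minor
#' (including property-damage-only), severe (hospitalised more than three
#' weeks), and fatal (killed at the scene or in hospital).
#'
#' @format Character vector of length 3, ordered from least to most severe.
#' @export
severity_levels <- c("minor", "severe", "fatal")

#' Seatbelt-use labels
#' @format Character vector of length 2.
#' @export
seatbelt_levels <- c("restrained", "unrestrained")

# columns that are never covariates
.reserved_cols <- c("outcome", "seatbelt", "period")

#' Covariate columns of a crash table
#'
#' By convention a crash table is a data frame with an `outcome` column
#' (factor over [severity_levels]), optional `seatbelt` and `period` label
#' columns, and binary 0/1 covariate columns.  Every non-reserved column is a
#' covariate.
#'
#' @param data A crash data frame.
#' @return Character vector of covariate column names.
#' @export
crash_covariates <- function(data) {
  setdiff(names(data), .reserved_cols)
}

#' Validate a crash table
#'
#' Checks the contract assumed by the estimation functions: an `outcome`
#' column with exactly the three severity levels, and all covariate columns
#' coded 0/1 with no missing values.  Missing values are rejected rather than
#' imputed.
#'
#' @param data A data frame of crash records, one row per crash.
#' @param require_labels If `TRUE`, also require `seatbelt` and `period`
#'   columns on every record (needed for subgroup splitting).
#' @return `data` invisibly, as a tibble with `outcome` converted to a factor
#'   over [severity_levels].
#' @export
validate_crash_data <- function(data, require_labels = FALSE) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) stop("crash table has no records", call. = FALSE)
  if (!"outcome" %in% names(data)) {
    stop("crash table must have an 'outcome' column", call. = FALSE)
  }
  data$outcome <- parse_outcome(data$outcome)
  if (anyNA(data$outcome)) {
    stop("outcome column contains values outside {1,2,3}/{minor,severe,fatal} ",
         "(first bad row: ", which(is.na(data$outcome))[1], ")", call. = FALSE)
  }
  if (require_labels) {
    for (col in c("seatbelt", "period")) {
      if (!col %in% names(data) || anyNA(data[[col]])) {
        stop("every record needs a non-missing '", col, "' label", call. = FALSE)
      }
    }
  }
  for (col in crash_covariates(data)) {
    if (col %in% c("seatbelt", "period")) next
    v <- data[[col]]
    if (!is.numeric(v)) {
      stop("covariate '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop("covariate '", col, "' has non-binary value in row ", bad[1],
           " (value ", v[bad[1]], ")", call. = FALSE)
    }
  }
  invisible(data)
}

parse_outcome <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    out <- factor(severity_levels[match(x, 1:3)], levels = severity_levels)
  } else {
    out <- factor(tolower(as.character(x)), levels = severity_levels)
  }
  out
}

#' Read a crash table from CSV
#'
#' Reads a comma-separated crash table (header row required).  The outcome
#' column may be coded `1/2/3` (minor/severe/fatal) or by label.  A YAML
#' variable dictionary may assign roles to columns; columns present in the
#' file but absent from the dictionary are reported (message) and kept as-is,
#' never silently dropped.
#'
#' @param path Path to a CSV file.
#' @param dictionary Optional variable dictionary: either a path to a YAML
#'   file or a list with elements `outcome`, and optionally `seatbelt`,
#'   `period` (column names in the file) and `covariates` (named list mapping
#'   column name to human-readable description).
#' @return A validated crash tibble.  The dictionary's covariate descriptions,
#'   if any, are attached as attribute `"dictionary"`.
#' @export
#' @examples
#' path <- system.file("extdata", "toy_crashes.csv", package = "severomix")
#' crashes <- read_crash_table(path)
#' dplyr::count(crashes, outcome)
read_crash_table <- function(path, dictionary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) stop("empty crash table: ", path, call. = FALSE)
  if (is.character(dictionary) && length(dictionary) == 1L) {
    dictionary <- yaml::read_yaml(dictionary)
  }
  if (!is.null(dictionary)) {
    rename_from <- c(outcome = dictionary$outcome,
                     seatbelt = dictionary$seatbelt,
                     period = dictionary$period)
    for (role in names(rename_from)) {
      src <- rename_from[[role]]
      if (!src %in% names(raw)) {
        stop("dictionary maps role '", role, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- role
    }
    known <- c(names(rename_from), names(dictionary$covariates))
    unknown <- setdiff(names(raw), known)
    if (length(unknown) > 0L) {
      message("columns not in dictionary (kept): ",
              paste(unknown, collapse = ", "))
    }
  }
  data <- validate_crash_data(raw)
  attr(data, "dictionary") <- dictionary$covariates
  data
}

#' Write a crash table to CSV
#'
#' Inverse of [read_crash_table()]: the outcome is written as `1/2/3`.
#'
#' @param data A crash tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crash_table <- function(data, path) {
  data <- validate_crash_data(data)
  out <- data
  out$outcome <- as.integer(out$outcome)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a crash table into seatbelt-by-period subgroups
#'
#' Partitions the records by `(seatbelt, period)`; with two seatbelt states
#' and three biennial periods this yields the six analysis subsets.
#'
#' @param data A crash tibble with `seatbelt` and `period` labels on every
#'   record.
#' @return A nested tibble with columns `seatbelt`, `period`, `n` and a
#'   list-column `data` holding each subgroup's records (label columns
#'   retained).  Subgroup sizes always sum to `nrow(data)`.
#' @export
split_subgroups <- function(data) {
  data <- validate_crash_data(data, require_labels = TRUE)
  nested <- tidyr::nest(dplyr::group_by(data, .data$seatbelt, .data$period))
  nested <- dplyr::ungroup(nested)
  nested$data <- purrr::pmap(nested, function(seatbelt, period, data) {
    dplyr::mutate(data, seatbelt = seatbelt, period = period,
                  .after = "outcome")
  })
  nested <- dplyr::arrange(nested, .data$seatbelt, .data$period)
  dplyr::mutate(nested, n = purrr::map_int(.data$data, nrow), .after = "period")
}

#' Descriptive statistics for a crash table
#'
#' Outcome counts and percentage shares, and per-covariate mean and standard
#' deviation (population SD equals `sqrt(p(1-p))` for an exactly-Bernoulli
#' column; the sample SD reported here differs only by the `n/(n-1)` factor).
#'
#' @param data A crash tibble.
#' @param percent_digits Digits for the percentage column (default 2, the
#'   usual reporting precision).
#' @return A list of class `"severity_descriptives"` with tibbles `outcome`
#'   (`severity`, `count`, `percent`) and `covariates` (`covariate`, `mean`,
#'   `sd`).
#' @export
descriptive_stats <- function(data, percent_digits = 2) {
  data <- validate_crash_data(data)
  n <- nrow(data)
  counts <- as.integer(table(data$outcome))
  outcome <- tibble::tibble(
    severity = factor(severity_levels, levels = severity_levels),
    count = counts,
    percent = round(100 * counts / n, percent_digits)
  )
  covs <- crash_covariates(data)
  covs <- covs[vapply(data[covs], is.numeric, logical(1))]
  covariates <- tibble::tibble(
    covariate = covs,
    mean = vapply(data[covs], mean, numeric(1)),
    sd = vapply(data[covs], stats::sd, numeric(1))
  )
  structure(list(outcome = outcome, covariates = covariates, n = n),
            class = "severity_descriptives")
}

#' @export
print.severity_descriptives <- function(x, ...) {
  cat("Crash descriptive statistics (N = ", x$n, ")\n\n", sep = "")
  ot <- x$outcome
  cat("Injury severity:\n")
  for (i in seq_len(nrow(ot))) {
    cat(sprintf("  %-8s %6d (%.2f%%)\n", ot$severity[i], ot$count[i],
                ot$percent[i]))
  }
  if (nrow(x$covariates) > 0L) {
    cat("\nCovariates (mean, SD):\n")
    cv <- x$covariates
    for (i in seq_len(nrow(cv))) {
      cat(sprintf("  %-20s %.3f (%.3f)\n", cv$covariate[i], cv$mean[i],
                  cv$sd[i]))
    }
  }
  invisible(x)
}

#' Pearson multicollinearity screen
#'
#' Computes pairwise Pearson correlations between covariate columns (the phi
#' coefficient for 0/1 columns) and flags every unordered pair whose absolute
#' correlation meets the threshold.  The screen only flags; removing
#' covariates is left to the analyst.
#'
#' @param data A crash tibble with at least two covariates.
#' @param threshold Absolute-correlation threshold in (0, 1]; defaults to the
#'   conventional 0.7 screen.
#' @return A tibble with columns `var1`, `var2`, `r`, sorted by `abs(r)`
#'   descending, containing all pairs with `abs(r) >= threshold`.
#'   Zero-variance columns (correlation undefined) are reported in the
#'   `"degenerate"` attribute and excluded from the pair list, with a warning.
#' @export
correlation_screen <- function(data, threshold = 0.7) {
  data <- validate_crash_data(data)
  stopifnot(threshold > 0, threshold <= 1)
  covs <- crash_covariates(data)
  covs <- covs[vapply(data[covs], is.numeric, logical(1))]
  if (length(covs) < 2L) stop("need at least two covariates", call. = FALSE)
  X <- as.matrix(data[covs])
  degenerate <- covs[apply(X, 2, stats::sd) == 0]
  if (length(degenerate) > 0L) {
    warning("zero-variance covariate(s), correlation undefined: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    covs <- setdiff(covs, degenerate)
    X <- X[, covs, drop = FALSE]
  }
  cm <- stats::cor(X)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = covs[pairs[, 1]],
    var2 = covs[pairs[, 2]],
    r = cm[pairs]
  )
  out <- dplyr::arrange(dplyr::filter(out, abs(.data$r) >= threshold),
                        dplyr::desc(abs(.data$r)))
  attr(out, "degenerate") <- degenerate
  out
}
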