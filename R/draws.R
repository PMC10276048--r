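#' Halton quasi-random sequence
#'
#' The radical-inverse sequence in a prime base: element `n` is obtained by
#' writing `n` in base `b` and mirroring its digits about the radix point.
#' Successive elements fill the unit interval far more evenly than
#' pseudo-random numbers, which is why simulated maximum likelihood converges
#' in far fewer draws with Halton sequences.
#'
#' @param base Prime base (2, 3, 5, ...).
#' @param count Number of elements to return.
#' @param discard Number of initial elements to skip; the first returned
#'   element is the radical inverse of `discard + 1`.
#' @return Numeric vector of `count` values in (0, 1).
#' @export
#' @examples
#' halton_sequence(2, 4)  # 0.5 0.25 0.75 0.125
halton_sequence <- function(base, count, discard = 0) {
  stopifnot(count >= 1, discard >= 0)
  if (!is_prime(base)) stop("base must be prime, got ", base, call. = FALSE)
  n <- discard + seq_len(count)
  h <- numeric(count)
  f <- 1 / base
  while (any(n > 0)) {
    h <- h + (n %% base) * f
    n <- n %/% base
    f <- f / base
  }
  h
}

is_prime <- function(x) {
  x <- as.integer(x)
  if (is.na(x) || x < 2L) return(FALSE)
  if (x < 4L) return(TRUE)
  if (x %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= x) {
    if (x %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

#' First `n` primes (Halton bases, one per random parameter)
#' @param n How many primes.
#' @return Integer vector of the first `n` primes: 2, 3, 5, ...
#' @export
halton_primes <- function(n) {
  primes <- integer(0)
  candidate <- 2L
  while (length(primes) < n) {
    if (is_prime(candidate)) primes <- c(primes, candidate)
    candidate <- candidate + 1L
  }
  primes
}

#' Transform uniform draws to mixing-distribution variates
#'
#' Inverse-CDF transforms: `"normal"` maps through the standard-normal
#' quantile function then `location + scale * z`; `"uniform"` to
#' `location + scale * (2u - 1)` (support `[location - scale,
#' location + scale]`); `"triangular"` to the symmetric triangular
#' distribution on the same support; `"lognormal"` to
#' `sign * exp(location + scale * z)`.
#'
#' @param u Uniform (0, 1) draws.
#' @param distribution One of `"normal"`, `"triangular"`, `"uniform"`,
#'   `"lognormal"`.
#' @param location,scale Distribution parameters (`scale >= 0`); defaults 0, 1
#'   give the standardised variate used inside the estimator.
#' @param sign For `"lognormal"`: +1 or -1.
#' @return Numeric vector of transformed draws.
#' @export
transform_draws <- function(u, distribution, location = 0, scale = 1,
                            sign = 1) {
  stopifnot(scale >= 0)
  distribution <- match.arg(distribution, .mixing_distributions)
  switch(distribution,
    normal = location + scale * stats::qnorm(u),
    uniform = location + scale * (2 * u - 1),
    triangular = location + scale * standard_triangular(u),
    lognormal = sign * exp(location + scale * stats::qnorm(u))
  )
}

# inverse CDF of the symmetric triangular distribution on [-1, 1]
standard_triangular <- function(u) {
  ifelse(u < 0.5, sqrt(2 * u) - 1, 1 - sqrt(2 * (1 - u)))
}

#' Build the per-observation draw matrix
#'
#' Random parameter `r` uses the `r`-th prime as its Halton base.  After
#' skipping `discard` initial points, observation `i` consumes sequence
#' elements `(i-1)*K + 1` to `i*K`, so observations get disjoint blocks and
#' the matrix is fully deterministic: the same `(N, distributions, K,
#' discard)` always reproduces it bit-for-bit.
#'
#' Uniforms are transformed to each random parameter's *standardised* variate
#' `nu` (standard normal for `"normal"` and `"lognormal"`, symmetric
#' triangular / uniform on `[-1, 1]` otherwise); location and scale are
#' applied later, inside the likelihood, where they carry the
#' heterogeneity-in-mean and -variance structure.
#'
#' @param n_obs Number of observations `N`.
#' @param distributions Character vector, the mixing distribution of each
#'   random parameter (length `R`).
#' @param k Draws per observation (`K`); the study default is 1000.
#' @param discard Initial Halton points skipped per base (default 100, where
#'   the sequence's early serial correlation lives).
#' @return Object of class `"draw_matrix"`: list with `values` (array
#'   `N x R x K` of standardised variates), `k`, `discard`, `bases`,
#'   `distributions`.
#' @export
make_draw_matrix <- function(n_obs, distributions, k, discard = 100) {
  stopifnot(n_obs >= 1, k >= 1)
  n_rand <- length(distributions)
  values <- array(numeric(0), dim = c(n_obs, n_rand, k))
  bases <- halton_primes(n_rand)
  if (n_rand > 0) {
    values <- array(NA_real_, dim = c(n_obs, n_rand, k))
    for (r in seq_len(n_rand)) {
      u <- halton_sequence(bases[r], n_obs * k, discard = discard)
      # element (i-1)*K + kk belongs to observation i, draw kk
      nu <- transform_draws(u, distributions[r])
      values[, r, ] <- matrix(nu, nrow = n_obs, ncol = k, byrow = TRUE)
    }
  }
  structure(list(values = values, k = k, discard = discard, bases = bases,
                 distributions = distributions),
            class = "draw_matrix")
}

#' @export
print.draw_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat("Halton draw matrix: ", d[1], " obs x ", d[2], " random parameter(s) x ",
      d[3], " draws (discard ", x$discard, ", bases ",
      paste(x$bases, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# N*K vector for random parameter r, draw-major stacking (obs index fastest),
# matching the likelihood engine's internal layout
draw_vector <- function(draws, r) {
  as.vector(draws$values[, r, ])
}
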