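# Internal computational core: model frame construction and the simulated
# log-likelihood engine (value + analytic gradient in one pass).
#
# Layout conventions.  With N observations, J alternatives and K draws, all
# draw-expanded quantities are (N*K) x J matrices stacked draw-major: row
# index  i + (kk-1)*N  is observation i, draw kk.  A length-N vector recycles
# correctly over that stacking, which is what keeps the engine allocation-light.

build_model_frame <- function(spec, data) {
  data <- validate_crash_data(data)
  report <- validate_spec(spec, data)
  if (!report$ok) {
    stop("invalid specification:\n  - ",
         paste(report$errors, collapse = "\n  - "), call. = FALSE)
  }
  n <- nrow(data)
  y <- match(as.character(data$outcome), spec$alternatives)
  covs <- spec_covariates(spec)
  X <- cbind(constant = rep(1, n),
             as.matrix(tibble::as_tibble(data)[covs]))
  pt <- param_table(spec)
  pidx <- stats::setNames(seq_len(nrow(pt)), pt$name)

  fixed <- pt[pt$block %in% c("constant", "fixed"), , drop = FALSE]
  fixed_terms <- purrr::map(seq_len(nrow(fixed)), function(i) {
    list(p = pidx[[fixed$name[i]]],
         col = match(fixed$covariate[i], colnames(X)),
         alt = match(fixed$alternative[i], spec$alternatives))
  })

  random_terms <- purrr::map(seq_len(nrow(spec$random)), function(r) {
    rd <- spec$random[r, ]
    lab <- sprintf("%s [%s]", rd$covariate, rd$alternative)
    ms <- rd$mean_shifters[[1]]
    vs <- rd$variance_shifters[[1]]
    list(
      r = r,
      col = match(rd$covariate, colnames(X)),
      alt = match(rd$alternative, spec$alternatives),
      distribution = rd$distribution,
      sign = rd$sign,
      M = X[, ms, drop = FALSE],
      SD = X[, vs, drop = FALSE],
      p_mean = pidx[[lab]],
      p_het_mean = unname(pidx[sprintf("%s : %s", lab, ms)]),
      p_sd = pidx[[sprintf("sd(%s)", lab)]],
      p_het_sd = unname(pidx[sprintf("sd(%s) : %s", lab, vs)])
    )
  })

  list(n = n, j = length(spec$alternatives), y = y, X = X,
       param_table = pt, fixed_terms = fixed_terms,
       random_terms = random_terms, spec = spec)
}

default_draws <- function(mf, k, discard = 100) {
  make_draw_matrix(mf$n, mf$spec$random$distribution, k = k, discard = discard)
}

# Simulated log-likelihood and (optionally) its analytic gradient.
# theta: named parameter vector in param_table order.
# Returns list(ll, grad, probs) where probs is the N x J matrix of
# draw-averaged choice probabilities.
mixl_engine <- function(theta, mf, draws = NULL, want_grad = FALSE,
                        want_probs = FALSE) {
  n <- mf$n; j <- mf$j; y <- mf$y; X <- mf$X
  n_rand <- length(mf$random_terms)
  k <- if (n_rand > 0L) draws$k else 1L
  nk <- n * k

  # systematic utility, draw-independent part
  vf <- matrix(0, n, j)
  for (tm in mf$fixed_terms) {
    vf[, tm$alt] <- vf[, tm$alt] + theta[tm$p] * X[, tm$col]
  }

  rand_state <- vector("list", n_rand)
  for (tm in mf$random_terms) {
    m_i <- theta[tm$p_mean] +
      if (length(tm$p_het_mean)) drop(tm$M %*% theta[tm$p_het_mean]) else 0
    e_i <- if (length(tm$p_het_sd)) {
      exp(drop(tm$SD %*% theta[tm$p_het_sd]))
    } else {
      rep(1, n)
    }
    s_i <- abs(theta[tm$p_sd]) * e_i
    if (tm$distribution != "lognormal") {
      vf[, tm$alt] <- vf[, tm$alt] + X[, tm$col] * m_i
    }
    rand_state[[tm$r]] <- list(m = m_i, e = e_i, s = s_i)
  }

  # expand over draws and add the draw-dependent parts
  if (n_rand > 0L) {
    v <- vf[rep(seq_len(n), k), , drop = FALSE]
    for (tm in mf$random_terms) {
      st <- rand_state[[tm$r]]
      nu <- draw_vector(draws, tm$r)
      if (tm$distribution == "lognormal") {
        coef <- tm$sign * exp(st$m + st$s * nu)
        rand_state[[tm$r]]$coef <- coef
        v[, tm$alt] <- v[, tm$alt] + X[, tm$col] * coef
      } else {
        v[, tm$alt] <- v[, tm$alt] + (X[, tm$col] * st$s) * nu
      }
    }
  } else {
    v <- vf
  }

  # logit kernel, overflow-guarded
  vmax <- v[, 1]
  for (jj in 2:j) vmax <- pmax(vmax, v[, jj])
  ev <- exp(v - vmax)
  denom <- rowSums(ev)
  p <- ev / denom

  # draw-averaged probabilities
  if (k > 1L) {
    pm <- matrix(NA_real_, n, j)
    for (jj in seq_len(j)) pm[, jj] <- rowMeans(matrix(p[, jj], n, k))
  } else {
    pm <- p
  }
  pm_y <- pm[cbind(seq_len(n), y)]
  floored <- pm_y < 1e-300
  pm_y_f <- pmax(pm_y, 1e-300)
  ll <- sum(log(pm_y_f))

  out <- list(ll = ll, n_floored = sum(floored))
  if (want_probs) out$probs <- pm
  if (!want_grad) return(out)

  # analytic gradient ------------------------------------------------------
  y_big <- rep(y, times = k)
  p_y_big <- p[cbind(seq_len(nk), y_big)]
  w <- p_y_big / (k * rep(pm_y_f, times = k))

  # e_mat[i, a] = 1[y_i = a] - sum_k w_ik P_ik(a)
  e_mat <- matrix(0, n, j)
  for (a in seq_len(j)) {
    ta <- w * p[, a]
    s_a <- if (k > 1L) rowSums(matrix(ta, n, k)) else ta
    e_mat[, a] <- (y == a) - s_a
  }

  grad <- numeric(nrow(mf$param_table))
  for (tm in mf$fixed_terms) {
    grad[tm$p] <- sum(X[, tm$col] * e_mat[, tm$alt])
  }
  for (tm in mf$random_terms) {
    st <- rand_state[[tm$r]]
    x_r <- X[, tm$col]
    sgn_sd <- sign(theta[tm$p_sd])
    if (tm$distribution == "lognormal") {
      nu <- draw_vector(draws, tm$r)
      resid <- (y_big == tm$alt) - p[, tm$alt]
      wf <- w * st$coef * resid
      e0 <- rowSums(matrix(wf, n, k))
      e1 <- rowSums(matrix(wf * nu, n, k))
    } else {
      nu <- draw_vector(draws, tm$r)
      resid <- (y_big == tm$alt) - p[, tm$alt]
      e0 <- e_mat[, tm$alt]
      e1 <- rowSums(matrix(w * nu * resid, n, k))
    }
    grad[tm$p_mean] <- sum(x_r * e0)
    if (length(tm$p_het_mean)) {
      for (ii in seq_along(tm$p_het_mean)) {
        grad[tm$p_het_mean[ii]] <- sum(x_r * tm$M[, ii] * e0)
      }
    }
    grad[tm$p_sd] <- sgn_sd * sum(x_r * st$e * e1)
    if (length(tm$p_het_sd)) {
      for (ii in seq_along(tm$p_het_sd)) {
        grad[tm$p_het_sd[ii]] <- sum(x_r * st$s * tm$SD[, ii] * e1)
      }
    }
  }
  out$grad <- grad
  out
}

#' Zero-initialised named parameter vector for a specification
#'
#' Convenient starting point for building true parameter vectors for the
#' synthetic-data generator or start values for [fit_mixed_logit()].
#'
#' @param spec A [severity_spec()].
#' @return Named numeric vector of zeros in [param_table()] order.
#' @export
params_template <- function(spec) {
  pt <- param_table(spec)
  stats::setNames(numeric(nrow(pt)), pt$name)
}

check_params <- function(theta, spec) {
  pt <- param_table(spec)
  if (is.null(names(theta))) {
    stopifnot(length(theta) == nrow(pt))
    return(stats::setNames(as.numeric(theta), pt$name))
  }
  missing <- setdiff(pt$name, names(theta))
  if (length(missing) > 0L) {
    stop("parameter(s) missing from vector: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(theta[pt$name]) |> stats::setNames(pt$name)
}
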