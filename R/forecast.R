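#' Predictive ensemble container
#'
#' Monte-Carlo draws from an s-step-ahead predictive distribution:
#' `draws` is an `R x s x n` array of counts; `lambda` (when available)
#' holds the per-draw conditional intensities, enabling Rao-Blackwellized
#' predictive pmfs.
#'
#' @param draws `R x s x n` integer array of simulated future counts.
#' @param lambda optional `R x s x n` array of the intensities the counts
#'   were drawn from.
#' @param origin forecast origin `T` (data are conditioned on through `T`).
#' @param model provenance label.
#' @return An object of class `predictive_ensemble`.
#' @export
predictive_ensemble <- function(draws, lambda = NULL, origin = NA_integer_,
                                model = "unknown") {
  if (length(dim(draws)) != 3L) stop("'draws' must be an R x s x n array")
  if (any(draws < 0) || any(draws != round(draws)))
    stop("ensemble draws must be non-negative integers")
  if (!is.null(lambda) && !all(dim(lambda) == dim(draws)))
    stop("'lambda' must match the dimensions of 'draws'")
  structure(list(draws = draws, lambda = lambda, origin = origin,
                 model = model, R = dim(draws)[1L], s = dim(draws)[2L],
                 n = dim(draws)[3L]),
            class = "predictive_ensemble")
}

#' @export
print.predictive_ensemble <- function(x, ...) {
  cat(sprintf("<predictive_ensemble: R = %d draws, s = %d horizons, n = %d series (%s)>\n",
              x$R, x$s, x$n, x$model))
  invisible(x)
}

#' Posterior predictive forecast from the state-space model
#'
#' Builds the s-step-ahead predictive distribution the Bayesian way: each
#' replicate samples a parameter draw from the retained posterior and a
#' terminal latent particle by its filter weight, propagates the latent
#' VAR forward `s` steps, and emits Poisson counts. Parameter uncertainty
#' is thereby folded into the forecast; the posterior is not re-estimated
#' between horizons.
#'
#' @param fit a [pmmh] result.
#' @param pf a stored [bootstrap_pf()] run on the same data (conventionally
#'   at the posterior median) supplying the terminal particle set.
#' @param s forecast horizon (`>= 1`), in time steps.
#' @param R number of Monte-Carlo replicates.
#' @return A [predictive_ensemble] with intensities attached.
#' @export
forecast_ssm <- function(fit, pf, s, R = 10000) {
  stopifnot(inherits(fit, "pmmh"), inherits(pf, "particle_filter"))
  if (s < 1) stop("forecast horizon must be >= 1")
  n <- fit$n
  if (fit$prior$n != pf$params$n) stop("dimension mismatch")
  m <- nrow(pf$last_particles)
  p <- m / n
  draws <- array(0L, c(R, s, n))
  lam <- array(0, c(R, s, n))
  idx_theta <- sample.int(nrow(fit$draws), R, replace = TRUE)
  idx_part <- sample.int(ncol(pf$last_particles), R, replace = TRUE,
                         prob = pf$last_weights)
  for (r in seq_len(R)) {
    pr <- ssm_trans_to_params(fit$draws_trans[idx_theta[r], ], n)
    C <- var_companion(pr$Phi)
    L <- chol_psd(pr$Sigma)
    h <- pf$last_particles[, idx_part[r]]
    if (length(h) < n * pr$p) h <- rep(h, length.out = n * pr$p)
    for (k in seq_len(s)) {
      h <- as.numeric(C %*% h)
      h[seq_len(n)] <- h[seq_len(n)] + as.numeric(L %*% stats::rnorm(n))
      l <- pr$beta * exp(h[seq_len(n)])
      lam[r, k, ] <- l
      draws[r, k, ] <- stats::rpois(n, l)
    }
  }
  predictive_ensemble(draws, lam, origin = pf$T, model = "ssm")
}

#' Forecast from a fitted observation-driven model
#'
#' Horizon one is the exact conditional distribution: the intensity
#' `lambda_{T+1}` (or `exp(nu_{T+1})`) follows deterministically from the
#' fitted recursion and the observed data. Later horizons are obtained by
#' stochastic path simulation — sampled counts are fed back into the
#' recursion — so that the full predictive distribution (not only its
#' mean) is available for scoring.
#'
#' @param fit a [maci_fit()] or [loglin_fit()] result, or bare
#'   [maci_params()] / [loglin_params()].
#' @param x the observed [count_series] the forecast conditions on.
#' @param s forecast horizon (`>= 1`).
#' @param R number of Monte-Carlo replicates.
#' @param model `"maci"` or `"loglinear"`; inferred from `fit` when
#'   possible.
#' @param nu_max explosion guard for the log-linear recursion.
#' @return A [predictive_ensemble] with intensities attached.
#' @export
forecast_obs_driven <- function(fit, x, s, R = 10000, model = NULL,
                                nu_max = 30) {
  if (s < 1) stop("forecast horizon must be >= 1")
  params <- if (inherits(fit, "maci_fit")) fit$params else fit
  if (is.null(model)) {
    model <- if (inherits(params, "loglin_params")) "loglinear" else "maci"
  }
  model <- match.arg(model, c("maci", "loglinear"))
  X <- as_count_matrix(x)
  n <- ncol(X); TT <- nrow(X)
  loglinear <- model == "loglinear"

  if (loglinear) {
    state_path <- loglin_filter(params, X, nu_max = nu_max)$nu
  } else {
    state_path <- maci_filter(params, X)
  }
  last_state <- state_path[TT, ]

  step <- function(state, x_prev) {
    if (loglinear) {
      as.numeric(params$omega + params$A %*% state +
                   params$B %*% log(x_prev + 1))
    } else {
      as.numeric(params$omega + params$A %*% state + params$B %*% x_prev)
    }
  }
  state1 <- step(last_state, X[TT, ])

  draws <- array(0L, c(R, s, n))
  lam <- array(0, c(R, s, n))
  for (r in seq_len(R)) {
    state <- state1
    x_prev <- NULL
    for (k in seq_len(s)) {
      if (k > 1L) state <- step(state, x_prev)
      if (loglinear && any(abs(state) > nu_max))
        stop("explosive log-intensity path in forecast replicate ", r)
      l <- if (loglinear) exp(state) else state
      lam[r, k, ] <- l
      x_prev <- stats::rpois(n, l)
      draws[r, k, ] <- x_prev
    }
  }
  predictive_ensemble(draws, lam, origin = TT, model = model)
}

#' Predictive probability mass function
#'
#' Marginal predictive pmf of one series at one horizon. When per-draw
#' intensities are available the Rao-Blackwellized mixture
#' `(1/R) sum_r Pois(k; lambda_r)` is used; otherwise empirical draw
#' frequencies. The support is `0..K`, auto-extended to cover both the
#' observed draws and the upper mixture quantile at mass `1 - 1e-9`.
#'
#' @param ens a [predictive_ensemble].
#' @param horizon horizon index in `1..s`.
#' @param series series index in `1..n`.
#' @param support optional upper support bound `K` (extended if too small).
#' @return Numeric vector `p` with `p[k + 1] = P(X = k)`, `k = 0..K`.
#' @export
predictive_pmf <- function(ens, horizon = 1, series = 1, support = NULL) {
  stopifnot(inherits(ens, "predictive_ensemble"))
  if (horizon < 1 || horizon > ens$s) stop("horizon out of range")
  if (series < 1 || series > ens$n) stop("series out of range")
  x <- ens$draws[, horizon, series]
  if (!is.null(ens$lambda)) {
    l <- ens$lambda[, horizon, series]
    K <- max(stats::qpois(1e-9, max(l), lower.tail = FALSE), max(x))
    if (!is.null(support)) K <- max(K, support)
    k <- 0:K
    p <- rowMeans(vapply(l, function(li) stats::dpois(k, li),
                         numeric(K + 1L)))
  } else {
    K <- max(x)
    if (!is.null(support)) K <- max(K, support)
    p <- tabulate(x + 1L, nbins = K + 1L) / length(x)
  }
  p
}

#' Per-horizon ensemble summary
#'
#' @param ens a [predictive_ensemble].
#' @param level central interval mass.
#' @return Data frame with one row per (horizon, series): predictive mean,
#'   median and central interval bounds.
#' @export
summarize_ensemble <- function(ens, level = 0.9) {
  stopifnot(inherits(ens, "predictive_ensemble"))
  a <- (1 - level) / 2
  out <- expand.grid(horizon = seq_len(ens$s), series = seq_len(ens$n))
  out$mean <- NA_real_; out$median <- NA_real_
  out$lower <- NA_real_; out$upper <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- ens$draws[, out$horizon[i], out$series[i]]
    q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE)
    out$mean[i] <- mean(x)
    out$median[i] <- q[2L]
    out$lower[i] <- q[1L]
    out$upper[i] <- q[3L]
  }
  out
}
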