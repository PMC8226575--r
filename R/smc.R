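#' Bootstrap particle filter for the Poisson state-space model
#'
#' Sequential Monte Carlo approximation of the filtering distributions and
#' of the (intractable) likelihood of the state-space model. Particles are
#' propagated from the latent VAR transition, weighted by the observation
#' density, and resampled every step. The per-step likelihood increment is
#' the log of the mean unnormalized weight, accumulated with log-sum-exp,
#' which makes the product an unbiased likelihood estimate — the property
#' particle Metropolis-Hastings relies on.
#'
#' A Gaussian-measurement variant (`observation = "gaussian"`, with
#' `X_t = h_t + N(0, obs_sd^2 I)` and a real-valued `x`) is provided for
#' validating the filter against the exact Kalman filter on the
#' linear-Gaussian analogue of the model.
#'
#' @param params an [ssm_params] object.
#' @param x a [count_series] (or, for the Gaussian variant, a numeric
#'   matrix), `T x n`.
#' @param n_particles number of particles `N >= 2`.
#' @param resample `"systematic"` (default) or `"multinomial"`.
#' @param observation `"poisson"` (the model) or `"gaussian"` (validation).
#' @param obs_sd measurement standard deviation for the Gaussian variant.
#' @param store keep the full per-step particle and weight history
#'   (required by [ffbs_sample()]); turn off inside long MCMC runs.
#' @param h_init optional fixed initial state (length `n * p`); default is
#'   the stationary VAR distribution (zeros when nonstationary).
#' @return An object of class `particle_filter`: `loglik`, `ess` (per-step
#'   effective sample sizes), `last_particles` (`n*p x N`), `last_weights`,
#'   and when `store = TRUE` also `particles` (`n*p x N x T` cube,
#'   pre-resampling), `weights` (`N x T`) and `ancestors`.
#' @export
bootstrap_pf <- function(params, x, n_particles,
                         resample = c("systematic", "multinomial"),
                         observation = c("poisson", "gaussian"),
                         obs_sd = 1, store = TRUE, h_init = NULL) {
  stopifnot(inherits(params, "ssm_params"), n_particles >= 2)
  resample <- match.arg(resample)
  observation <- match.arg(observation)
  X <- if (observation == "poisson") as_count_matrix(x) else as.matrix(x)
  storage.mode(X) <- "double"
  n <- params$n; p <- params$p; m <- n * p
  if (ncol(X) != n) stop("series dimension mismatch")

  C <- var_companion(params$Phi)
  L <- matrix(0, m, n)
  L[seq_len(n), ] <- chol_psd(params$Sigma)
  if (is.null(h_init)) {
    st <- ssm_stationarity(params)
    if (st$stationary) {
      h1_mean <- numeric(m)
      h1_L <- chol_psd(var_stationary_cov(params$Phi, params$Sigma))
    } else {
      h1_mean <- numeric(m)
      h1_L <- matrix(0, m, m)
    }
  } else {
    h1_mean <- as.numeric(h_init)
    h1_L <- matrix(0, m, m)
  }

  s <- cpp_seed_pair()
  r <- pf_cpp(X, params$beta, C, L, h1_mean, h1_L, as.integer(n_particles),
              if (observation == "poisson") 0L else 1L, obs_sd,
              if (resample == "systematic") 0L else 1L, store, s[1L], s[2L])
  if (!isTRUE(r$ok))
    stop("particle filter degenerated (all weights underflowed) at t = ",
         r$t_fail)
  r$ok <- NULL
  r$params <- params
  r$observation <- observation
  r$obs_sd <- obs_sd
  r$n_particles <- as.integer(n_particles)
  r$T <- nrow(X)
  class(r) <- "particle_filter"
  r
}

#' @export
print.particle_filter <- function(x, ...) {
  cat(sprintf("<particle_filter: N = %d, T = %d, loglik = %.4f, min ESS = %.1f>\n",
              x$n_particles, x$T, x$loglik, min(x$ess)))
  invisible(x)
}

#' Resampling indices from a weight vector
#'
#' Draws `length(w)` ancestor indices with expected multiplicity
#' `N * w_i`. The systematic scheme uses a single uniform offset, so each
#' index appears either `floor(N w_i)` or `ceiling(N w_i)` times; the
#' multinomial scheme draws independently.
#'
#' @param w non-negative weight vector (normalized internally).
#' @param scheme `"systematic"` or `"multinomial"`.
#' @return Integer vector of indices in `1..length(w)`.
#' @export
resample_indices <- function(w, scheme = c("systematic", "multinomial")) {
  scheme <- match.arg(scheme)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  s <- cpp_seed_pair()
  resample_cpp(w, if (scheme == "systematic") 0L else 1L, s[1L], s[2L])
}

#' Forward-filtering backward-sampling smoother
#'
#' Draws latent trajectories from the particle approximation of the
#' smoothing distribution: a terminal state is sampled from the final
#' filter, then each earlier state is sampled with weight proportional to
#' `W_k^i f(h_{k+1} | h_k^i)` under the VAR transition density. Requires a
#' filter run with `store = TRUE` and lag order `p = 1` (the transition
#' covariance must be full rank). Cost is `O(N T)` per sampled path.
#'
#' @param pf a stored [bootstrap_pf()] result.
#' @param n_paths number of smoothed trajectories to draw.
#' @return `n x T x n_paths` array of latent trajectories (class
#'   `smoothed_paths` with attribute `n_paths`).
#' @export
ffbs_sample <- function(pf, n_paths) {
  stopifnot(inherits(pf, "particle_filter"))
  if (is.null(pf$particles))
    stop("filter was run with store = FALSE; FFBS needs the full history")
  if (pf$params$p != 1L)
    stop("backward smoothing is implemented for p = 1")
  SigInv <- solve(pf$params$Sigma)
  s <- cpp_seed_pair()
  paths <- ffbs_sample_cpp(pf$particles, pf$weights, pf$params$Phi[[1L]],
                           SigInv, as.integer(n_paths), s[1L], s[2L])
  structure(paths, class = "smoothed_paths")
}

#' Marginal smoothing weights
#'
#' Backward recursion for the marginal smoothed weights `W_{k|T}^i` over
#' the stored filter particles; each column sums to one. Cost `O(N^2 T)`.
#'
#' @param pf a stored [bootstrap_pf()] result with `p = 1`.
#' @return `N x T` matrix of smoothing weights.
#' @export
ffbs_weights <- function(pf) {
  stopifnot(inherits(pf, "particle_filter"))
  if (is.null(pf$particles))
    stop("filter was run with store = FALSE; FFBS needs the full history")
  if (pf$params$p != 1L)
    stop("backward smoothing is implemented for p = 1")
  ffbs_marginal_cpp(pf$particles, pf$weights, pf$params$Phi[[1L]],
                    solve(pf$params$Sigma))
}

#' Smoothed latent means
#'
#' Convenience: per-time-step posterior means of the latent state, either
#' from marginal smoothing weights (`method = "marginal"`) or from
#' backward-sampled paths.
#'
#' @param pf a stored [bootstrap_pf()] result with `p = 1`.
#' @param method `"marginal"` or `"sample"`.
#' @param n_paths paths to draw for `method = "sample"`.
#' @return `T x n` matrix of smoothed means.
#' @export
ffbs_means <- function(pf, method = c("marginal", "sample"), n_paths = 500) {
  method <- match.arg(method)
  n <- pf$params$n
  if (method == "marginal") {
    W <- ffbs_weights(pf)
    TT <- ncol(W)
    out <- matrix(0, TT, n)
    for (k in seq_len(TT)) {
      Pk <- matrix(pf$particles[, , k], nrow = dim(pf$particles)[1L])
      out[k, ] <- Pk[seq_len(n), , drop = FALSE] %*% W[, k]
    }
    out
  } else {
    paths <- ffbs_sample(pf, n_paths)
    t(apply(paths, c(1L, 2L), mean))[, seq_len(n), drop = FALSE]
  }
}
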