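#' Nonlinear Poisson state-space model parameters
#'
#' Parameter-driven count model: `X_it ~ Poisson(lambda_it)` with
#' `lambda_t = beta * exp(h_t)` and a latent Gaussian VAR(p) process
#' `h_t = Phi_1 h_{t-1} + ... + Phi_p h_{t-p} + eta_t`,
#' `eta_t ~ N(0, Sigma_eta)`. For two series the innovation covariance is
#' parameterized by `(sigma1, sigma2, rho)` with off-diagonal
#' `rho * sigma1 * sigma2`.
#'
#' @param beta positive scale vector, length `n` (intensity units).
#' @param Phi an `n x n` matrix (p = 1) or list of `n x n` matrices.
#' @param Sigma full innovation covariance matrix; alternatively give
#'   `sigma` and `rho`.
#' @param sigma vector of innovation standard deviations (length `n`).
#' @param rho correlation between the two innovations (bivariate case
#'   only), `|rho| < 1`.
#' @return An object of class `ssm_params` with elements `beta`, `Phi`
#'   (list), `Sigma`, `p`, `n`.
#' @export
ssm_params <- function(beta, Phi, Sigma = NULL, sigma = NULL, rho = NULL) {
  beta <- as.numeric(beta)
  n <- length(beta)
  if (any(beta <= 0)) stop("'beta' must be > 0 elementwise")
  if (is.matrix(Phi)) Phi <- list(Phi)
  if (!all(vapply(Phi, function(m) all(dim(m) == n), logical(1L))))
    stop("each Phi must be ", n, " x ", n)
  if (is.null(Sigma)) {
    if (is.null(sigma)) stop("give 'Sigma' or ('sigma', 'rho')")
    if (length(sigma) != n || any(sigma <= 0))
      stop("'sigma' must be a positive vector of length ", n)
    if (n == 2L) {
      if (is.null(rho)) rho <- 0
      if (abs(rho) >= 1) stop("|rho| must be < 1")
      Sigma <- matrix(c(sigma[1L]^2, rho * sigma[1L] * sigma[2L],
                        rho * sigma[1L] * sigma[2L], sigma[2L]^2), 2L, 2L)
    } else {
      if (!is.null(rho) && any(rho != 0))
        stop("scalar 'rho' is only supported for n = 2; pass 'Sigma'")
      Sigma <- diag(sigma^2, n)
    }
  }
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(unname(Sigma), tol = 1e-10))
    stop("'Sigma' must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("'Sigma' must be positive semidefinite")
  structure(list(beta = beta, Phi = Phi, Sigma = (Sigma + t(Sigma)) / 2,
                 p = length(Phi), n = n),
            class = "ssm_params")
}

#' Intensity map of the state-space model
#'
#' `lambda_t = beta * exp(h_t)` elementwise.
#'
#' @param beta positive scale vector.
#' @param h latent vector (or `T x n` matrix of latent states).
#' @return Intensities with the shape of `h`.
#' @export
ssm_intensity <- function(beta, h) {
  if (any(beta <= 0)) stop("'beta' must be > 0")
  if (is.matrix(h)) sweep(exp(h), 2L, beta, "*") else beta * exp(h)
}

# Companion matrix of the VAR(p) coefficient list.
var_companion <- function(Phi) {
  p <- length(Phi); n <- nrow(Phi[[1L]])
  C <- matrix(0, n * p, n * p)
  C[seq_len(n), ] <- do.call(cbind, Phi)
  if (p > 1L)
    C[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  C
}

#' Stationarity of the latent VAR
#'
#' The VAR(p) is stationary when all companion-matrix eigenvalues lie
#' strictly inside the unit circle (the equivalent of the characteristic
#' roots lying outside it).
#'
#' @param Phi an `n x n` matrix, a list of them, or an [ssm_params] object.
#' @return List with `stationary` (logical), `max_modulus` and the complex
#'   `eigenvalues`.
#' @export
ssm_stationarity <- function(Phi) {
  if (inherits(Phi, "ssm_params")) Phi <- Phi$Phi
  if (is.matrix(Phi)) Phi <- list(Phi)
  ev <- eigen(var_companion(Phi), only.values = TRUE)$values
  list(stationary = max(Mod(ev)) < 1, max_modulus = max(Mod(ev)),
       eigenvalues = ev)
}

# Stationary covariance of the companion-stacked VAR state by the discrete
# Lyapunov equation, solved through the Kronecker (vec) form.
var_stationary_cov <- function(Phi, Sigma) {
  if (is.matrix(Phi)) Phi <- list(Phi)
  C <- var_companion(Phi)
  m <- nrow(C); n <- nrow(Sigma)
  Q <- matrix(0, m, m)
  Q[seq_len(n), seq_len(n)] <- Sigma
  G <- matrix(solve(diag(m * m) - kronecker(C, C), as.vector(Q)), m, m)
  (G + t(G)) / 2
}

#' Granger-causal structure of the latent process
#'
#' Reads the zero pattern of the VAR coefficient matrices: series `j`'s
#' latent component Granger-causes series `i`'s when any `Phi_k[i, j]` is
#' non-zero.
#'
#' @param Phi an `n x n` matrix, a list of them, or an [ssm_params] object.
#' @param tol entries with absolute value below `tol` count as zero.
#' @return List with the logical adjacency matrix `causes` (`causes[i, j]`:
#'   j causes i) and a character vector `edges` of "j -> i" descriptions.
#' @export
ssm_granger <- function(Phi, tol = 0) {
  if (inherits(Phi, "ssm_params")) Phi <- Phi$Phi
  if (is.matrix(Phi)) Phi <- list(Phi)
  n <- nrow(Phi[[1L]])
  adj <- Reduce("|", lapply(Phi, function(m) abs(m) > tol))
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- if (nrow(idx)) paste0(idx[, 2L], " -> ", idx[, 1L]) else character()
  list(causes = adj, edges = edges)
}

#' Simulate from the Poisson state-space model
#'
#' Draws the Gaussian VAR latent path, then conditionally independent
#' Poisson counts with intensity `beta * exp(h_t)`. The initial latent
#' state is drawn from the stationary VAR distribution (discrete Lyapunov
#' equation) when the process is stationary, else started at zero.
#'
#' @param params an [ssm_params] object.
#' @param T number of time points.
#' @param h_init optional fixed initial latent vector (length `n * p`,
#'   most recent block first); overrides the stationary draw.
#' @return List with `counts` (a [count_series]) and `h` (`T x n` latent
#'   path).
#' @export
ssm_simulate <- function(params, T, h_init = NULL) {
  stopifnot(inherits(params, "ssm_params"))
  n <- params$n; p <- params$p
  st <- ssm_stationarity(params)
  if (!st$stationary)
    warning("latent VAR is not stationary (max eigenvalue modulus ",
            signif(st$max_modulus, 4), ")")
  C <- var_companion(params$Phi)
  m <- n * p
  Lsig <- chol_psd(params$Sigma)
  if (is.null(h_init)) {
    if (st$stationary) {
      G0 <- var_stationary_cov(params$Phi, params$Sigma)
      h_state <- as.numeric(chol_psd(G0) %*% stats::rnorm(m))
    } else {
      h_state <- numeric(m)
    }
  } else {
    if (length(h_init) != m) stop("'h_init' must have length n * p = ", m)
    h_state <- as.numeric(h_init)
  }
  H <- matrix(0, T, n)
  X <- matrix(0L, T, n)
  for (t in seq_len(T)) {
    if (t > 1L) {
      eta <- as.numeric(Lsig %*% stats::rnorm(n))
      h_state <- as.numeric(C %*% h_state)
      h_state[seq_len(n)] <- h_state[seq_len(n)] + eta
    }
    H[t, ] <- h_state[seq_len(n)]
    X[t, ] <- stats::rpois(n, params$beta * exp(H[t, ]))
  }
  list(counts = count_series(X), h = H)
}

# Lower-triangular square root tolerating semidefinite input.
chol_psd <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(v), length(v))
}
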