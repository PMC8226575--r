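#' Linear conditional-intensity (MACI / INGARCH) parameters
#'
#' Parameters of the linear multivariate autoregressive conditional
#' intensity model: counts are conditionally Poisson with intensity
#' `lambda_t = omega + A lambda_{t-1} + B X_{t-1}`. All entries must be
#' non-negative so the intensity stays positive; the spectral norm of
#' `A + B` below one marks the stationary region.
#'
#' @param omega positive intercept vector, length `n`.
#' @param A `n x n` non-negative feedback matrix (on past intensities).
#' @param B `n x n` non-negative observation matrix (on past counts).
#' @param lambda0 optional non-negative shared-shock intensity for
#'   contemporaneous dependence when simulating (`joint = "common_shock"`).
#' @return An object of class `maci_params`.
#' @export
maci_params <- function(omega, A, B, lambda0 = 0) {
  omega <- as.numeric(omega)
  n <- length(omega)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == n) || !all(dim(B) == n))
    stop("A and B must be ", n, " x ", n, " matrices")
  if (any(omega < 0) || any(A < 0) || any(B < 0) || lambda0 < 0)
    stop("all MACI parameters must be non-negative")
  structure(list(omega = omega, A = A, B = B, lambda0 = as.numeric(lambda0),
                 n = n),
            class = "maci_params")
}

#' Stationarity check for the linear model
#'
#' Returns the spectral norm of `A + B` and whether it is below one (the
#' sufficient condition for stationarity of the intensity recursion).
#'
#' @param params a [maci_params] object.
#' @return List with `stationary` (logical) and `norm` (spectral norm).
#' @export
maci_stationarity <- function(params) {
  stopifnot(inherits(params, "maci_params"))
  nrm <- norm(params$A + params$B, type = "2")
  list(stationary = nrm < 1, norm = nrm)
}

maci_default_init <- function(params) {
  st <- maci_stationarity(params)
  if (st$stationary) {
    as.numeric(solve(diag(params$n) - params$A - params$B, params$omega))
  } else {
    params$omega
  }
}

#' Filter the conditional intensity path
#'
#' Runs the recursion `lambda_t = omega + A lambda_{t-1} + B X_{t-1}` over
#' an observed series. `lambda_1` is set to `init` (default: the
#' unconditional mean `(I - A - B)^{-1} omega` when stationary, else
#' `omega`).
#'
#' @param params a [maci_params] object.
#' @param x a [count_series] or count matrix, `T x n`.
#' @param init positive starting intensity vector.
#' @return `T x n` matrix of intensities, strictly positive.
#' @export
maci_filter <- function(params, x, init = NULL) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- maci_default_init(params)
  if (any(init <= 0)) stop("initial intensity must be > 0")
  r <- maci_qml_cpp(params$omega, params$A, params$B, X, init,
                    FALSE, FALSE)
  if (!isTRUE(r$ok)) stop("non-positive intensity at t = ", r$t_fail)
  colnames(r$lambda) <- colnames(X)
  r$lambda
}

#' Poisson quasi-log-likelihood of the linear model
#'
#' `sum_t sum_i (x_it log lambda_it - lambda_it)`; the factorial term of the
#' full Poisson likelihood is dropped as it does not involve the parameters.
#'
#' @inheritParams maci_filter
#' @return Scalar quasi-log-likelihood.
#' @export
maci_loglik <- function(params, x, init = NULL) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- maci_default_init(params)
  if (any(init <= 0)) stop("initial intensity must be > 0")
  r <- maci_qml_cpp(params$omega, params$A, params$B, X, init, FALSE, FALSE)
  if (!isTRUE(r$ok)) stop("non-positive intensity at t = ", r$t_fail)
  r$loglik
}

#' Analytic score of the linear quasi-log-likelihood
#'
#' The score `S_T = sum_t (d lambda_t / d theta)' D_t^{-1} (X_t - lambda_t)`
#' with `D_t = diag(lambda_t)`, computed by the exact derivative recursions
#' of the intensity with respect to `theta = (omega, vec(A), vec(B))`.
#' Derivative states are initialized at zero (`lambda_1` is treated as a
#' fixed constant).
#'
#' @inheritParams maci_filter
#' @return Numeric vector of length `n(1 + 2n)`.
#' @export
maci_score <- function(params, x, init = NULL) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- maci_default_init(params)
  r <- maci_qml_cpp(params$omega, params$A, params$B, X, init, TRUE, FALSE)
  if (!isTRUE(r$ok)) stop("non-positive intensity at t = ", r$t_fail)
  stats::setNames(as.numeric(r$score), maci_theta_names(params$n))
}

#' Curvature matrices of the linear quasi-likelihood
#'
#' Returns `H` (the negative Hessian of the quasi-log-likelihood, including
#' the exact second-derivative recursion of the intensity) and `G` (the
#' conditional information matrix under the working Poisson assumption,
#' i.e. with the conditional count covariance set to `D_t`). The sandwich
#' covariance of the QML estimator is `H^{-1} G H^{-1}`.
#'
#' @inheritParams maci_filter
#' @return List with symmetric `d x d` matrices `H` and `G`.
#' @export
maci_information <- function(params, x, init = NULL) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- maci_default_init(params)
  r <- maci_qml_cpp(params$omega, params$A, params$B, X, init, TRUE, TRUE)
  if (!isTRUE(r$ok)) stop("non-positive intensity at t = ", r$t_fail)
  nm <- maci_theta_names(params$n)
  dimnames(r$H) <- dimnames(r$G) <- list(nm, nm)
  list(H = (r$H + t(r$H)) / 2, G = (r$G + t(r$G)) / 2)
}

maci_theta_names <- function(n) {
  c(paste0("omega", seq_len(n)),
    paste0("a", as.vector(outer(seq_len(n), seq_len(n),
                                function(r, c) paste0(r, c)))),
    paste0("b", as.vector(outer(seq_len(n), seq_len(n),
                                function(r, c) paste0(r, c)))))
}

maci_pack <- function(params) c(params$omega, as.vector(params$A),
                                as.vector(params$B))

maci_unpack <- function(theta, n, lambda0 = 0) {
  maci_params(theta[seq_len(n)],
              matrix(theta[n + seq_len(n * n)], n, n),
              matrix(theta[n + n * n + seq_len(n * n)], n, n),
              lambda0 = lambda0)
}

#' Simulate from the linear conditional-intensity model
#'
#' Draws counts forward through the intensity recursion. With
#' `joint = "independent"` the series are conditionally independent
#' Poisson; with `joint = "common_shock"` a shared Poisson shock with
#' intensity `params$lambda0` is added to every series each period, which
#' induces positive contemporaneous correlation.
#'
#' @param params a [maci_params] object.
#' @param T number of time points.
#' @param joint contemporaneous dependence structure.
#' @param init starting intensity (default: unconditional mean).
#' @return A [count_series] of dimension `T x n`.
#' @export
maci_simulate <- function(params, T, joint = c("independent", "common_shock"),
                          init = NULL) {
  joint <- match.arg(joint)
  st <- maci_stationarity(params)
  if (!st$stationary)
    warning("parameters outside the stationary region (||A + B||_2 = ",
            signif(st$norm, 4), ")")
  if (is.null(init)) init <- maci_default_init(params)
  n <- params$n
  X <- matrix(0L, T, n)
  lam <- init
  for (t in seq_len(T)) {
    if (t > 1L)
      lam <- params$omega + params$A %*% lam + params$B %*% X[t - 1L, ]
    xt <- stats::rpois(n, lam)
    if (joint == "common_shock" && params$lambda0 > 0)
      xt <- xt + stats::rpois(1L, params$lambda0)
    X[t, ] <- xt
  }
  count_series(X)
}

#' Quasi-maximum likelihood fit of the linear model
#'
#' Maximizes the Poisson quasi-log-likelihood over the non-negative orthant
#' with `optim(method = "L-BFGS-B")` and the analytic score as gradient.
#' Starting values follow the univariate-first strategy: each series is fit
#' on its own, and cross terms start at a small positive value. The
#' intensity is initialized at the per-series sample mean, held fixed
#' across evaluations so the objective is exactly differentiable.
#'
#' Standard errors are sandwich, `H^{-1} G H^{-1}`. Parameters whose
#' estimates land on the lower bound are flagged as boundary-active:
#' inference for those is unreliable.
#'
#' @param x a [count_series] or count matrix.
#' @param start optional [maci_params] starting point (skips the univariate
#'   stage).
#' @param lower lower box bound enforcing positivity.
#' @param control passed to [stats::optim()].
#' @return An object of class `maci_fit`: `params` (the estimate),
#'   `theta`, `se`, `vcov`, `loglik`, `score`, `convergence`,
#'   `boundary` (logical vector), `n`, `T`.
#' @export
maci_fit <- function(x, start = NULL, lower = 1e-8,
                     control = list(maxit = 500)) {
  X <- as_count_matrix(x)
  n <- ncol(X); TT <- nrow(X)
  d <- n * (1 + 2 * n)
  if (TT <= d / n + 2) stop("series too short to fit ", d, " parameters")
  init <- pmax(colMeans(X), 1e-3)

  if (is.null(start)) {
    theta0 <- maci_univariate_start(X, lower)
  } else {
    theta0 <- pmax(maci_pack(start), lower)
  }

  negll <- function(th) {
    r <- maci_qml_cpp(th[seq_len(n)], matrix(th[n + seq_len(n^2)], n, n),
                      matrix(th[n + n^2 + seq_len(n^2)], n, n), X, init,
                      FALSE, FALSE)
    if (!isTRUE(r$ok)) return(1e10)
    -r$loglik
  }
  neggr <- function(th) {
    r <- maci_qml_cpp(th[seq_len(n)], matrix(th[n + seq_len(n^2)], n, n),
                      matrix(th[n + n^2 + seq_len(n^2)], n, n), X, init,
                      TRUE, FALSE)
    if (!isTRUE(r$ok)) return(rep(0, d))
    -as.numeric(r$score)
  }
  opt <- stats::optim(theta0, negll, neggr, method = "L-BFGS-B",
                      lower = lower, control = control)

  theta <- opt$par
  params <- maci_unpack(theta, n)
  boundary <- theta <= lower * 1.5
  names(boundary) <- maci_theta_names(n)
  if (any(boundary))
    warning("parameters on the positivity boundary: ",
            paste(names(boundary)[boundary], collapse = ", "),
            " (standard errors there are unreliable)")
  info <- maci_information(params, X, init)
  vc <- sandwich_vcov(info$H, info$G)
  structure(list(params = params, theta = stats::setNames(theta,
                                                          maci_theta_names(n)),
                 se = sqrt(pmax(diag(vc), 0)), vcov = vc,
                 loglik = -opt$value,
                 score = maci_score(params, X, init),
                 convergence = opt$convergence, boundary = boundary,
                 init = init, n = n, T = TT, model = "maci"),
            class = "maci_fit")
}

maci_univariate_start <- function(X, lower) {
  n <- ncol(X)
  om <- numeric(n); aa <- numeric(n); bb <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[, i, drop = FALSE]
    initi <- pmax(mean(xi), 1e-3)
    f <- function(th) {
      r <- maci_qml_cpp(th[1L], matrix(th[2L], 1L, 1L),
                        matrix(th[3L], 1L, 1L), xi, initi, FALSE, FALSE)
      if (!isTRUE(r$ok)) return(1e10)
      -r$loglik
    }
    o <- stats::optim(c(max(mean(xi) * 0.4, 0.05), 0.2, 0.2), f,
                      method = "L-BFGS-B", lower = lower,
                      upper = c(Inf, 0.98, 0.98))
    om[i] <- o$par[1L]; aa[i] <- o$par[2L]; bb[i] <- o$par[3L]
  }
  A <- matrix(1e-3, n, n); diag(A) <- aa
  B <- matrix(1e-3, n, n); diag(B) <- bb
  c(om, as.vector(A), as.vector(B))
}

sandwich_vcov <- function(H, G) {
  Hi <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
  Hi %*% G %*% Hi
}

# Moore-Penrose fallback for near-singular curvature (boundary fits).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.maci_fit <- function(x, ...) {
  cat(sprintf("<%s_fit: n = %d, T = %d, quasi-loglik = %.3f, convergence = %d>\n",
              x$model, x$n, x$T, x$loglik, x$convergence))
  tab <- data.frame(estimate = x$theta, se = x$se)
  if (!is.null(x$boundary)) tab$boundary <- x$boundary
  print(tab)
  invisible(x)
}
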