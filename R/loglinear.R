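#' Log-linear count autoregression parameters
#'
#' Parameters of the log-linear model: counts are conditionally Poisson
#' with log-intensity `nu_t = omega + A nu_{t-1} + B log(X_{t-1} + 1)`,
#' `lambda_t = exp(nu_t)`. Coefficients are unrestricted in sign, which
#' is the model's advantage over the linear MACI recursion.
#'
#' @param omega real intercept vector, length `n`.
#' @param A `n x n` feedback matrix (on past log-intensities).
#' @param B `n x n` observation matrix (on past log-counts).
#' @param lambda0 optional non-negative shared-shock intensity used when
#'   simulating with `joint = "common_shock"`.
#' @return An object of class `loglin_params`.
#' @export
loglin_params <- function(omega, A, B, lambda0 = 0) {
  omega <- as.numeric(omega)
  n <- length(omega)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == n) || !all(dim(B) == n))
    stop("A and B must be ", n, " x ", n, " matrices")
  if (lambda0 < 0) stop("'lambda0' must be >= 0")
  structure(list(omega = omega, A = A, B = B, lambda0 = as.numeric(lambda0),
                 n = n),
            class = "loglin_params")
}

#' Stability check for the log-linear model
#'
#' Evaluates the partial sum `sum_{j=0}^{J} ||A^j B||_2`; the model is
#' stationary and weakly dependent when the full sum is below one. When
#' `||A||_2 < 1` the geometric tail bound
#' `||A||_2^{J+1} ||B||_2 / (1 - ||A||_2)` is added, making the answer
#' exact up to that bound; otherwise a diverging partial sum decides and a
#' partial sum below one is flagged undecided.
#'
#' @param params a [loglin_params] object.
#' @param J truncation order of the sum (`>= 1`).
#' @return List with `stable` (logical or `NA` when undecided), `value`
#'   (partial sum plus tail bound) and `partial_sum`.
#' @export
loglin_stability <- function(params, J = 50) {
  stopifnot(inherits(params, "loglin_params"), J >= 1)
  nA <- norm(params$A, type = "2")
  Aj <- diag(params$n)
  s <- 0
  for (j in 0:J) {
    s <- s + norm(Aj %*% params$B, type = "2")
    Aj <- Aj %*% params$A
  }
  if (nA < 1) {
    tail <- nA^(J + 1) * norm(params$B, type = "2") / (1 - nA)
    list(stable = (s + tail) < 1, value = s + tail, partial_sum = s)
  } else {
    list(stable = if (s >= 1) FALSE else NA, value = s, partial_sum = s)
  }
}

loglin_default_init <- function(params) params$omega

#' Filter the log-intensity path
#'
#' Runs `nu_t = omega + A nu_{t-1} + B log(X_{t-1} + 1)` over an observed
#' series with `nu_1 = init` (default `omega`). Because the coefficients
#' are unrestricted the path can explode; filtering aborts with an error
#' naming the first offending time point once any `|nu_it|` exceeds
#' `nu_max` (default 30, i.e. intensities around `1e13`).
#'
#' @param params a [loglin_params] object.
#' @param x a [count_series] or count matrix.
#' @param init starting log-intensity vector.
#' @param nu_max explosion guard on `|nu|`.
#' @return List with `nu` (`T x n`) and `lambda = exp(nu)`.
#' @export
loglin_filter <- function(params, x, init = NULL, nu_max = 30) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- loglin_default_init(params)
  r <- loglin_qml_cpp(params$omega, params$A, params$B, X, init,
                      FALSE, FALSE, nu_max)
  if (!isTRUE(r$ok)) stop("explosive log-intensity path at t = ", r$t_fail)
  colnames(r$nu) <- colnames(X)
  list(nu = r$nu, lambda = exp(r$nu))
}

#' Quasi-log-likelihood, score and curvature of the log-linear model
#'
#' `loglin_loglik` evaluates `sum_t sum_i (x_it nu_it - exp(nu_it))`;
#' `loglin_score` the analytic score
#' `sum_t (d nu_t / d theta)' (X_t - exp(nu_t))` via the same derivative
#' recursions as the linear model with `log(X_{t-1} + 1)` in place of
#' `X_{t-1}`; `loglin_information` returns the negative Hessian `H` (exact,
#' including second derivatives of `nu`) and the conditional information
#' `G = sum_t sum_i exp(nu_it) (d nu_it)(d nu_it)'`.
#'
#' @inheritParams loglin_filter
#' @return Scalar, `d`-vector, or list of `d x d` matrices respectively,
#'   with `theta = (omega, vec(A), vec(B))`, `d = n(1 + 2n)`.
#' @export
loglin_loglik <- function(params, x, init = NULL, nu_max = 30) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- loglin_default_init(params)
  r <- loglin_qml_cpp(params$omega, params$A, params$B, X, init,
                      FALSE, FALSE, nu_max)
  if (!isTRUE(r$ok)) stop("explosive log-intensity path at t = ", r$t_fail)
  r$loglik
}

#' @rdname loglin_loglik
#' @export
loglin_score <- function(params, x, init = NULL, nu_max = 30) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- loglin_default_init(params)
  r <- loglin_qml_cpp(params$omega, params$A, params$B, X, init,
                      TRUE, FALSE, nu_max)
  if (!isTRUE(r$ok)) stop("explosive log-intensity path at t = ", r$t_fail)
  stats::setNames(as.numeric(r$score), maci_theta_names(params$n))
}

#' @rdname loglin_loglik
#' @export
loglin_information <- function(params, x, init = NULL, nu_max = 30) {
  X <- as_count_matrix(x)
  if (is.null(init)) init <- loglin_default_init(params)
  r <- loglin_qml_cpp(params$omega, params$A, params$B, X, init,
                      TRUE, TRUE, nu_max)
  if (!isTRUE(r$ok)) stop("explosive log-intensity path at t = ", r$t_fail)
  nm <- maci_theta_names(params$n)
  dimnames(r$H) <- dimnames(r$G) <- list(nm, nm)
  list(H = (r$H + t(r$H)) / 2, G = (r$G + t(r$G)) / 2)
}

#' Simulate from the log-linear model
#'
#' Draws counts through the log-intensity recursion, conditionally
#' independent Poisson across series or with an added common Poisson shock
#' (`joint = "common_shock"`, intensity `params$lambda0`). Simulation stops
#' with an error if the log-intensity explodes.
#'
#' @param params a [loglin_params] object.
#' @param T number of time points.
#' @param joint contemporaneous dependence structure.
#' @param init starting log-intensity (default `omega`).
#' @param nu_max explosion guard on `|nu|`.
#' @return A [count_series] of dimension `T x n`.
#' @export
loglin_simulate <- function(params, T,
                            joint = c("independent", "common_shock"),
                            init = NULL, nu_max = 30) {
  joint <- match.arg(joint)
  if (is.null(init)) init <- loglin_default_init(params)
  n <- params$n
  X <- matrix(0L, T, n)
  nu <- init
  for (t in seq_len(T)) {
    if (t > 1L)
      nu <- params$omega + params$A %*% nu + params$B %*% log(X[t - 1L, ] + 1)
    if (any(abs(nu) > nu_max))
      stop("explosive log-intensity path at t = ", t)
    xt <- stats::rpois(n, exp(nu))
    if (joint == "common_shock" && params$lambda0 > 0)
      xt <- xt + stats::rpois(1L, params$lambda0)
    X[t, ] <- xt
  }
  count_series(X)
}

#' Quasi-maximum likelihood fit of the log-linear model
#'
#' Unconstrained maximization of the quasi-log-likelihood by BFGS with the
#' analytic score. Because estimation of this model is known to be
#' sensitive to starting values, a multi-start scheme is used: the first
#' start comes from univariate fits of each series (cross terms at zero),
#' followed by `n_starts - 1` random perturbations of it; the best
#' converged likelihood wins, ties broken by the smallest parameter norm.
#' The log-intensity is initialized at `log(xbar + 1)`, held fixed across
#' evaluations. Standard errors are sandwich `H^{-1} G H^{-1}`.
#'
#' @param x a [count_series] or count matrix.
#' @param start optional [loglin_params] used as the first start.
#' @param n_starts number of optimizer starts.
#' @param diagonal_A restrict the feedback matrix `A` to its diagonal
#'   (each series' log-intensity feeds back only on itself; cross-series
#'   dynamics enter through `B`). This is the specification whose
#'   coefficients applied studies conventionally report.
#' @param nu_max explosion guard on `|nu|` during filtering.
#' @param control passed to [stats::optim()].
#' @return An object of class `loglin_fit` (same shape as [maci_fit()]:
#'   `params`, `theta`, `se`, `vcov`, `loglik`, `score`, `convergence`,
#'   plus per-start diagnostics in `starts`). Under `diagonal_A` the fixed
#'   off-diagonal entries have estimate 0 and standard error `NA`.
#' @export
loglin_fit <- function(x, start = NULL, n_starts = 5, diagonal_A = FALSE,
                       nu_max = 30, control = list(maxit = 500)) {
  X <- as_count_matrix(x)
  n <- ncol(X); TT <- nrow(X)
  d <- n * (1 + 2 * n)
  init <- log(colMeans(X) + 1)
  free <- seq_len(d)
  if (diagonal_A) {
    offdiag <- n + which(as.vector(row(diag(n)) != col(diag(n))))
    free <- setdiff(free, offdiag)
  }
  expand <- function(thf) {
    th <- numeric(d); th[free] <- thf; th
  }

  theta0 <- if (is.null(start)) loglin_univariate_start(X) else
    maci_pack(start)
  starts <- list(theta0[free])
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- theta0[free] + stats::rnorm(length(free), 0, 0.1)
  }

  negll <- function(thf) {
    th <- expand(thf)
    r <- loglin_qml_cpp(th[seq_len(n)], matrix(th[n + seq_len(n^2)], n, n),
                        matrix(th[n + n^2 + seq_len(n^2)], n, n), X, init,
                        FALSE, FALSE, nu_max)
    if (!isTRUE(r$ok)) return(1e10)
    -r$loglik
  }
  neggr <- function(thf) {
    th <- expand(thf)
    r <- loglin_qml_cpp(th[seq_len(n)], matrix(th[n + seq_len(n^2)], n, n),
                        matrix(th[n + n^2 + seq_len(n^2)], n, n), X, init,
                        TRUE, FALSE, nu_max)
    if (!isTRUE(r$ok)) return(rep(0, length(free)))
    -as.numeric(r$score)[free]
  }

  results <- lapply(starts, function(th0) {
    tryCatch(stats::optim(th0, negll, neggr, method = "BFGS",
                          control = control),
             error = function(e) list(value = Inf, convergence = 99L,
                                      message = conditionMessage(e)))
  })
  vals <- vapply(results, function(r) r$value, numeric(1L))
  ok <- vals < 1e9
  if (!any(ok)) {
    status <- vapply(results, function(r)
      if (!is.null(r$message)) r$message else paste("convergence",
                                                    r$convergence),
      character(1L))
    stop("all optimizer starts failed:\n  ",
         paste(seq_along(status), status, sep = ": ", collapse = "\n  "))
  }
  best <- which(vals == min(vals[ok]) & ok)
  if (length(best) > 1L) {
    nrm <- vapply(best, function(i) sum(results[[i]]$par^2), numeric(1L))
    best <- best[which.min(nrm)]
  }
  opt <- results[[best[1L]]]

  theta <- expand(opt$par)
  params <- loglin_params(theta[seq_len(n)],
                          matrix(theta[n + seq_len(n^2)], n, n),
                          matrix(theta[n + n^2 + seq_len(n^2)], n, n))
  info <- loglin_information(params, X, init, nu_max)
  vc <- sandwich_vcov(info$H[free, free], info$G[free, free])
  se <- rep(NA_real_, d)
  se[free] <- sqrt(pmax(diag(vc), 0))
  structure(list(params = params,
                 theta = stats::setNames(theta, maci_theta_names(n)),
                 se = stats::setNames(se, maci_theta_names(n)), vcov = vc,
                 free = free,
                 loglik = -opt$value,
                 score = loglin_score(params, X, init, nu_max),
                 convergence = opt$convergence,
                 starts = data.frame(value = -vals,
                                     converged = vapply(results, function(r)
                                       isTRUE(r$convergence == 0),
                                       logical(1L))),
                 init = init, n = n, T = TT, model = "loglin"),
            class = c("loglin_fit", "maci_fit"))
}

loglin_univariate_start <- function(X) {
  n <- ncol(X)
  om <- numeric(n); aa <- numeric(n); bb <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[, i, drop = FALSE]
    initi <- log(mean(xi) + 1)
    f <- function(th) {
      r <- loglin_qml_cpp(th[1L], matrix(th[2L], 1L, 1L),
                          matrix(th[3L], 1L, 1L), xi, initi, FALSE, FALSE, 30)
      if (!isTRUE(r$ok)) return(1e10)
      -r$loglik
    }
    o <- stats::optim(c(initi * 0.4, 0.2, 0.2), f, method = "Nelder-Mead")
    om[i] <- o$par[1L]; aa[i] <- o$par[2L]; bb[i] <- o$par[3L]
  }
  A <- matrix(0, n, n); diag(A) <- aa
  B <- matrix(0, n, n); diag(B) <- bb
  c(om, as.vector(A), as.vector(B))
}
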