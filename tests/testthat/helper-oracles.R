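# Independent numerical oracles used across the suite.

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

# central finite-difference Jacobian of a vector function (rows = f comps)
fd_jac <- function(f, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a), 1))

# Trivariate-reduction bivariate pmf in its closed binomial-coefficient
# form: exp(-(l1+l2+l0)) l1^x1 l2^x2 / (x1! x2!) *
#   sum_i C(x1,i) C(x2,i) i! (l0/(l1 l2))^i
cshock_pmf_closed <- function(x1, x2, l1, l2, l0) {
  i <- 0:min(x1, x2)
  s <- sum(choose(x1, i) * choose(x2, i) * factorial(i) * (l0 / (l1 * l2))^i)
  exp(-(l1 + l2 + l0)) * l1^x1 * l2^x2 / (factorial(x1) * factorial(x2)) * s
}

# Exact Kalman filter/smoother for the linear-Gaussian analogue
#   h_t = Phi h_{t-1} + eta_t, eta ~ N(0, Sigma); y_t = h_t + N(0, R)
# with the stationary initial distribution h_1 ~ N(0, P0).
kalman_filter <- function(Y, Phi, Sigma, obs_sd, P0) {
  TT <- nrow(Y); n <- ncol(Y)
  R <- diag(obs_sd^2, n)
  m <- numeric(n); P <- P0
  ll <- 0
  mf <- matrix(0, TT, n)
  Pf <- vector("list", TT)
  mp <- matrix(0, TT, n)
  Pp <- vector("list", TT)
  for (t in seq_len(TT)) {
    if (t > 1L) {
      m <- as.numeric(Phi %*% m)
      P <- Phi %*% P %*% t(Phi) + Sigma
    }
    mp[t, ] <- m; Pp[[t]] <- P
    S <- P + R
    v <- Y[t, ] - m
    ll <- ll - 0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
                        sum(v * solve(S, v)))
    K <- P %*% solve(S)
    m <- m + as.numeric(K %*% v)
    P <- P - K %*% P
    mf[t, ] <- m; Pf[[t]] <- (P + t(P)) / 2
  }
  list(loglik = ll, mf = mf, Pf = Pf, mp = mp, Pp = Pp)
}

kalman_smoother <- function(kf, Phi) {
  TT <- nrow(kf$mf)
  ms <- kf$mf
  Ps <- kf$Pf[[TT]]
  for (t in (TT - 1L):1L) {
    J <- kf$Pf[[t]] %*% t(Phi) %*% solve(kf$Pp[[t + 1L]])
    ms[t, ] <- kf$mf[t, ] + as.numeric(J %*% (ms[t + 1L, ] - kf$mp[t + 1L, ]))
  }
  ms
}

# random admissible parameter points for the derivative checks
random_maci_params <- function() {
  A <- diag(runif(2, 0.1, 0.3)) + matrix(runif(4, 0, 0.08), 2, 2)
  B <- diag(runif(2, 0.1, 0.3)) + matrix(runif(4, 0, 0.08), 2, 2)
  maci_params(runif(2, 0.3, 1), A, B)
}

random_loglin_params <- function() {
  loglin_params(runif(2, -0.2, 0.4),
                matrix(runif(4, -0.25, 0.25), 2, 2),
                matrix(runif(4, -0.25, 0.25), 2, 2))
}

theta_of <- function(params) c(params$omega, as.vector(params$A),
                               as.vector(params$B))
theta_to_maci <- function(th) maci_params(th[1:2], matrix(th[3:6], 2, 2),
                                          matrix(th[7:10], 2, 2))
theta_to_loglin <- function(th) loglin_params(th[1:2], matrix(th[3:6], 2, 2),
                                              matrix(th[7:10], 2, 2))
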