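test_that("intensity filtering handles degenerate and decoupled cases", {
  x <- count_series(matrix(c(1L, 2L, 0L, 3L, 1L, 1L), 3, 2))
  p0 <- maci_params(c(0.7, 1.2), matrix(0, 2, 2), matrix(0, 2, 2))
  lam <- maci_filter(p0, x)
  expect_true(all(abs(sweep(lam, 2, c(0.7, 1.2))) < 1e-12))

  # a12 = b12 = 0: series 1's intensity ignores series 2 entirely
  p <- maci_params(c(0.5, 0.5),
                   matrix(c(0.3, 0.1, 0.0, 0.3), 2, 2),
                   matrix(c(0.2, 0.1, 0.0, 0.2), 2, 2))
  set.seed(3)
  x1 <- matrix(rpois(40, 2), 20, 2)
  x2 <- x1; x2[, 2] <- rev(x2[, 2])
  init <- c(1, 1)
  l1 <- maci_filter(p, count_series(x1), init)
  l2 <- maci_filter(p, count_series(x2), init)
  expect_equal(l1[, 1], l2[, 1], tolerance = 1e-12)
  expect_error(maci_filter(p, count_series(x1), c(-1, 1)), "initial")
})

test_that("quasi-log-likelihood matches hand values and drops the factorial", {
  x <- count_series(matrix(c(1L, 2L), 2, 1))
  p <- maci_params(1, matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(maci_loglik(p, x), -2, tolerance = 1e-12)
  # equals log full Poisson likelihood plus the factorial terms
  lam <- maci_filter(p, x)
  full <- sum(dpois(unclass(x), lam, log = TRUE))
  expect_equal(maci_loglik(p, x), full + sum(lgamma(unclass(x) + 1)),
               tolerance = 1e-10)
})

test_that("analytic score and curvature match finite differences", {
  set.seed(21)
  p <- random_maci_params()
  x <- maci_simulate(p, 60)
  init <- colMeans(unclass(x))
  f <- function(th) maci_loglik(theta_to_maci(th), x, init)
  g <- function(th) maci_score(theta_to_maci(th), x, init)
  th <- theta_of(p)
  expect_lt(rel_err(maci_score(p, x, init), fd_grad(f, th)), 1e-6)
  info <- maci_information(p, x, init)
  Hfd <- -fd_jac(g, th)
  expect_lt(rel_err(info$H, (Hfd + t(Hfd)) / 2), 1e-5)
  expect_gte(min(eigen(info$G, symmetric = TRUE)$values), -1e-8)
  # A = 0 kills the omega recursion: d lambda_t / d omega = I for all t
  p0 <- maci_params(c(0.5, 0.8), matrix(0, 2, 2),
                    matrix(0.2, 2, 2))
  sc <- maci_score(p0, x, init)
  lam <- maci_filter(p0, x, init)
  # derivative states are zero at t = 1, so the t = 1 term is excluded
  expect_equal(sc[1:2], colSums((unclass(x) / lam - 1)[-1, ]),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("stationarity check returns the spectral norm of A + B", {
  z <- matrix(0, 2, 2)
  expect_equal(maci_stationarity(maci_params(c(1, 1), z, z))$norm, 0)
  s1 <- maci_stationarity(maci_params(c(1, 1), diag(0.6, 2), diag(0.5, 2)))
  expect_equal(s1$norm, 1.1, tolerance = 1e-12)
  expect_false(s1$stationary)
  s2 <- maci_stationarity(maci_params(c(1, 1), diag(0.25, 2), diag(0.25, 2)))
  expect_equal(s2$norm, 0.5, tolerance = 1e-12)
  expect_true(s2$stationary)
})

test_that("simulation reproduces the unconditional mean and shock correlation", {
  # A = B = 0: i.i.d. Poisson(omega)
  set.seed(8)
  p0 <- maci_params(c(2, 4), matrix(0, 2, 2), matrix(0, 2, 2))
  x0 <- maci_simulate(p0, 5000)
  expect_lt(abs(mean(x0[, 1]) - 2), 4 * sqrt(2 / 5000))
  expect_lt(abs(cor(x0[, 1], x0[, 2])), 3 / sqrt(5000))

  # long-run mean of the filtered intensity equals (I - A - B)^{-1} omega
  p <- maci_params(c(1, 1), diag(0.3, 2), diag(0.3, 2))
  set.seed(9)
  x <- maci_simulate(p, 2e4)
  mu <- solve(diag(2) - p$A - p$B, p$omega)
  lam <- maci_filter(p, x)
  expect_lt(max(abs(colMeans(lam) - mu)), 0.12)
  expect_lt(max(abs(colMeans(unclass(x)) - mu)), 0.12)

  # common shock induces positive contemporaneous correlation
  ps <- maci_params(c(1, 1), diag(0.2, 2), diag(0.2, 2), lambda0 = 1)
  set.seed(10)
  xs <- maci_simulate(ps, 4000, joint = "common_shock")
  expect_gt(cor(xs[, 1], xs[, 2]), 0.15)
})

test_that("QML fitting recovers simulated parameters and flags boundaries", {
  set.seed(14)
  truth <- maci_params(c(0.3, 0.2),
                       matrix(c(0.3, 0.05, 0.0, 0.35), 2, 2),
                       matrix(c(0.35, 0.1, 0.05, 0.3), 2, 2))
  x <- maci_simulate(truth, 2000)
  fit <- suppressWarnings(maci_fit(x))
  expect_equal(fit$convergence, 0)
  th0 <- theta_of(truth)
  covered <- abs(fit$theta - th0) <= 3 * pmax(fit$se, 1e-4)
  expect_gte(mean(covered), 0.8)
  # realized-sample optimality over the truth
  expect_gte(fit$loglik, maci_loglik(truth, x, fit$init) - 1e-6)
  # scaled score near zero at the optimum (away from active bounds)
  free <- !fit$boundary
  expect_lt(max(abs(fit$score[free])) / fit$T, 1e-4)

  # a series of all zeros: boundary warning but no crash
  xz <- count_series(cbind(unclass(x)[1:300, 1], rep(0L, 300)))
  expect_warning(fz <- maci_fit(xz), "boundary")
  expect_s3_class(fz, "maci_fit")
})
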