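test_that("degenerate dynamics reduce the filter to the exact likelihood", {
  set.seed(51)
  x <- count_series(matrix(rpois(60, c(1, 2)), 30, 2, byrow = TRUE))
  p <- ssm_params(c(1, 2), matrix(0, 2, 2), Sigma = diag(0, 2))
  pf <- bootstrap_pf(p, x, 50, h_init = c(0, 0))
  exact <- sum(dpois(unclass(x), matrix(c(1, 2), 30, 2, byrow = TRUE),
                     log = TRUE))
  expect_equal(pf$loglik, exact, tolerance = 1e-10)
  # all particles identical, weights uniform
  expect_true(all(abs(pf$weights - 1 / 50) < 1e-14))
})

test_that("weights are normalized and the ESS is bounded by N", {
  set.seed(52)
  p <- dgp_catalog()$SSM1$params
  x <- ssm_simulate(p, 80)$counts
  pf <- bootstrap_pf(p, x, 200)
  expect_true(all(abs(colSums(pf$weights) - 1) < 1e-12))
  expect_true(all(pf$ess >= 1 - 1e-9 & pf$ess <= 200 + 1e-9))
  expect_true(is.finite(pf$loglik))
})

test_that("resampling schemes have the right multiplicity properties", {
  w <- c(0.5, 0.3, 0.15, 0.05)
  # one weight = 1: every index equals that particle
  expect_true(all(resample_indices(c(0, 1, 0), "systematic") == 2L))
  expect_true(all(resample_indices(c(0, 1, 0), "multinomial") == 2L))

  # systematic: multiplicity of index i is floor(Nw_i) or ceiling(Nw_i)
  set.seed(53)
  N <- 40
  wN <- rep(w, each = 10) / 10
  for (r in 1:50) {
    idx <- resample_indices(wN, "systematic")
    mult <- tabulate(idx, nbins = N)
    expect_true(all(mult >= floor(N * wN) & mult <= ceiling(N * wN)))
  }

  # multinomial with uniform weights: counts pass a chi-square check
  set.seed(54)
  counts <- integer(4)
  for (r in 1:2500) {
    idx <- resample_indices(rep(0.25, 4), "multinomial")
    counts <- counts + tabulate(idx, nbins = 4)
  }
  total <- sum(counts)
  chisq <- sum((counts - total / 4)^2 / (total / 4))
  expect_lt(chisq, qchisq(0.999, df = 3))
})

test_that("filter log-likelihood agrees with the exact Kalman value on the linear-Gaussian analogue", {
  set.seed(61)
  Phi <- matrix(c(0.5, 0.3, 0.0, 0.5), 2, 2)
  Sigma <- matrix(c(0.25, 0.3 * 0.25, 0.3 * 0.25, 0.25), 2, 2)
  obs_sd <- 0.7
  p <- ssm_params(c(1, 1), Phi, Sigma = Sigma)
  P0 <- countcast:::var_stationary_cov(list(Phi), Sigma)
  # simulate the linear-Gaussian system
  TT <- 60
  h <- matrix(0, TT, 2)
  h[1, ] <- as.numeric(countcast:::chol_psd(P0) %*% rnorm(2))
  Ls <- countcast:::chol_psd(Sigma)
  for (t in 2:TT)
    h[t, ] <- as.numeric(Phi %*% h[t - 1, ] + Ls %*% rnorm(2))
  y <- h + matrix(rnorm(TT * 2, 0, obs_sd), TT, 2)

  kf <- kalman_filter(y, Phi, Sigma, obs_sd, P0)
  lls <- replicate(10, bootstrap_pf(p, y, 1000, observation = "gaussian",
                                    obs_sd = obs_sd, store = FALSE)$loglik)
  expect_lt(abs(mean(lls) - kf$loglik), 3 * max(sd(lls), 0.05))

  # estimator variance shrinks as N grows
  set.seed(62)
  v <- vapply(c(100, 400, 1600), function(N) {
    var(replicate(12, bootstrap_pf(p, y, N, observation = "gaussian",
                                   obs_sd = obs_sd, store = FALSE)$loglik))
  }, numeric(1))
  expect_lt(v[3], v[1])
})

test_that("backward smoothing matches the Kalman smoother and sums to one", {
  set.seed(63)
  Phi <- diag(0.6, 2)
  Sigma <- diag(0.3, 2)
  obs_sd <- 0.6
  p <- ssm_params(c(1, 1), Phi, Sigma = Sigma)
  P0 <- countcast:::var_stationary_cov(list(Phi), Sigma)
  TT <- 40
  h <- matrix(0, TT, 2)
  h[1, ] <- as.numeric(countcast:::chol_psd(P0) %*% rnorm(2))
  Ls <- countcast:::chol_psd(Sigma)
  for (t in 2:TT)
    h[t, ] <- as.numeric(Phi %*% h[t - 1, ] + Ls %*% rnorm(2))
  y <- h + matrix(rnorm(TT * 2, 0, obs_sd), TT, 2)

  kf <- kalman_filter(y, Phi, Sigma, obs_sd, P0)
  ks <- kalman_smoother(kf, Phi)

  pf <- bootstrap_pf(p, y, 800, observation = "gaussian", obs_sd = obs_sd)
  W <- ffbs_weights(pf)
  expect_true(all(abs(colSums(W) - 1) < 1e-10))
  sm <- ffbs_means(pf, method = "marginal")
  expect_lt(mean(abs(sm - ks)), 0.08)
  sm2 <- ffbs_means(pf, method = "sample", n_paths = 400)
  expect_lt(mean(abs(sm2 - ks)), 0.1)
})

test_that("a single-particle filter smooths to its own filtered path", {
  set.seed(64)
  p <- dgp_catalog()$SSM1$params
  x <- ssm_simulate(p, 30)$counts
  pf <- bootstrap_pf(p, x, 2)
  paths <- ffbs_sample(pf, 3)
  # every smoothed path is supported on the stored particles
  for (k in 1:3) {
    for (t in 1:30) {
      d <- min(colSums(abs(pf$particles[, , t] - paths[, t, k])))
      expect_lt(d, 1e-12)
    }
  }
})
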