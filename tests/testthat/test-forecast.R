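test_that("degenerate SSM posterior forecasts Poisson(beta) at every horizon", {
  set.seed(81)
  beta <- c(1.5, 3)
  p <- ssm_params(beta, matrix(0, 2, 2), Sigma = diag(1e-12, 2))
  x <- ssm_simulate(p, 50, h_init = c(0, 0))$counts
  # near-point-mass posterior built from a tiny-variance prior chain
  prior <- ssm_prior(2, beta_var = 1e-8, phi_sd = 1e-6, logsigma_sd = 1e-6,
                     atanhrho_sd = 1e-6)
  # center the prior at the truth by shifting the start; with essentially
  # zero prior variance the chain stays at the start
  fit <- pmmh(x, prior = prior, n_iter = 300, warmup = 100,
              likelihood = "none", start = p)
  pf <- bootstrap_pf(p, x, 100, h_init = c(0, 0))
  ens <- forecast_ssm(fit, pf, s = 3, R = 4000)
  for (k in 1:3) {
    m <- apply(ens$draws[, k, ], 2, mean)
    expect_lt(abs(m[1] - beta[1]), 4 * sqrt(beta[1] / 4000))
    expect_lt(abs(m[2] - beta[2]), 4 * sqrt(beta[2] / 4000))
    pm <- predictive_pmf(ens, k, 1)
    # posterior is a point mass up to the 1e-4 prior sd on log beta
    expect_lt(max(abs(pm - dpois(seq_along(pm) - 1, beta[1]))), 1e-3)
  }
  expect_error(forecast_ssm(fit, pf, s = 0), ">= 1")
})

test_that("prior-zero-variance chains stay put", {
  # sanity for the construction above: the near-degenerate prior pins draws
  set.seed(82)
  p <- ssm_params(c(2, 2), diag(0.2, 2), sigma = c(0.3, 0.3), rho = 0)
  x <- ssm_simulate(p, 30)$counts
  prior <- ssm_prior(2, beta_var = 1e-8, phi_sd = 1e-6, logsigma_sd = 1e-6,
                     atanhrho_sd = 1e-6)
  fit <- pmmh(x, prior = prior, n_iter = 200, warmup = 50,
              likelihood = "none", start = p)
  expect_lt(max(abs(fit$draws[, "beta1"] - 2)), 0.05)
})

test_that("observation-driven forecasts match the conditional intensity", {
  set.seed(83)
  # A = B = 0: every horizon is Poisson(omega)
  p0 <- maci_params(c(2, 1), matrix(0, 2, 2), matrix(0, 2, 2))
  x <- maci_simulate(p0, 100)
  ens0 <- forecast_obs_driven(p0, x, s = 3, R = 4000)
  for (k in 1:3)
    expect_lt(abs(mean(ens0$draws[, k, 1]) - 2), 4 * sqrt(2 / 4000))

  # horizon-1 mean equals the deterministic lambda_{T+1}
  p <- maci_params(c(0.5, 0.5), diag(0.3, 2),
                   matrix(c(0.2, 0.1, 0.0, 0.3), 2, 2))
  set.seed(84)
  x <- maci_simulate(p, 200)
  lam <- maci_filter(p, x)
  lam_T1 <- as.numeric(p$omega + p$A %*% lam[200, ] + p$B %*% unclass(x)[200, ])
  ens <- forecast_obs_driven(p, x, s = 4, R = 8000)
  expect_equal(apply(ens$lambda[, 1, ], 2, mean), lam_T1, tolerance = 1e-10)
  expect_lt(max(abs(apply(ens$draws[, 1, ], 2, mean) - lam_T1)),
            4 * sqrt(max(lam_T1) / 8000))

  # multi-step MACI mean follows the linear plug-in recursion
  mu <- lam_T1
  means <- matrix(0, 4, 2)
  means[1, ] <- mu
  for (k in 2:4) {
    mu <- as.numeric(p$omega + (p$A + p$B) %*% mu)
    means[k, ] <- mu
  }
  mc <- apply(ens$draws, c(2, 3), mean)
  expect_lt(max(abs(mc - means)), 0.1)
})

test_that("log-linear forecasts use the exact one-step log-intensity", {
  p <- dgp_catalog()$LL2$params
  set.seed(85)
  x <- loglin_simulate(p, 150)
  f <- loglin_filter(p, x)
  nu_T1 <- as.numeric(p$omega + p$A %*% f$nu[150, ] +
                        p$B %*% log(unclass(x)[150, ] + 1))
  ens <- forecast_obs_driven(p, x, s = 2, R = 2000, model = "loglinear")
  expect_equal(apply(ens$lambda[, 1, ], 2, mean), exp(nu_T1),
               tolerance = 1e-10)
})

test_that("predictive pmfs are proper and consistent with draw frequencies", {
  set.seed(86)
  p <- maci_params(c(1, 2), diag(0.2, 2), diag(0.3, 2))
  x <- maci_simulate(p, 150)
  ens <- forecast_obs_driven(p, x, s = 2, R = 5000)
  pm <- predictive_pmf(ens, 2, 1)
  expect_true(all(pm >= 0))
  expect_lt(abs(sum(pm) - 1), 1e-8)
  # Rao-Blackwellized mixture vs empirical frequencies
  emp <- tabulate(ens$draws[, 2, 1] + 1L, nbins = length(pm)) / ens$R
  se <- sqrt(pmax(pm * (1 - pm), 1e-12) / ens$R)
  expect_true(all(abs(pm - emp) <= 4 * se + 1e-3))
})

test_that("ensemble summaries and validation behave", {
  set.seed(87)
  d <- array(rpois(200 * 2 * 2, 3), c(200, 2, 2))
  ens <- predictive_ensemble(d, model = "test")
  s <- summarize_ensemble(ens)
  expect_equal(nrow(s), 4)
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  expect_error(predictive_ensemble(array(-1, c(2, 2, 2))), "non-negative")
})
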