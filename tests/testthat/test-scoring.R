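pois_pmf <- function(lambda, K) dpois(0:K, lambda)
point_mass <- function(x, K) { p <- numeric(K + 1); p[x + 1] <- 1; p }

test_that("scoring rules match closed forms on simple predictives", {
  p1 <- pois_pmf(1, 60)
  expect_equal(score_log(p1, 0), 1, tolerance = 1e-12)
  # point mass at the outcome
  pm <- point_mass(3, 10)
  expect_equal(score_log(pm, 3), 0)
  expect_equal(score_quadratic(pm, 3), -1)
  expect_equal(score_spherical(pm, 3), -1)
  expect_equal(score_rps(pm, 3), 0)
  expect_equal(score_ses(pm, 3), 0)
  # uniform over 0..9
  pu <- rep(0.1, 10)
  expect_equal(score_quadratic(pu, 4), -0.1, tolerance = 1e-12)
  # any proper p: log score >= 0
  expect_gte(score_log(p1, 3), 0)
  # zero-probability outcome warns and returns Inf
  expect_warning(v <- score_log(point_mass(0, 5), 3), "zero")
  expect_identical(v, Inf)
})

test_that("Dawid-Sebastiani and squared-error scores evaluate as defined", {
  expect_equal(score_dss(0, 1, 2), 4)
  expect_equal(score_dss(5, 2, 5), 2 * log(2))
  expect_equal(score_dss(0, 1, 2, as_printed = TRUE), 2)
  expect_error(score_dss(0, 0, 1), "> 0")
  p <- pois_pmf(2.5, 40)
  expect_equal(score_ses(p, 4), (4 - 2.5)^2, tolerance = 1e-8)
  # dss orders like ses when sigma is constant across forecasts
  s1 <- score_dss(2, 1.5, 4); s2 <- score_dss(3, 1.5, 4)
  expect_gt(s1, s2)
})

test_that("rps matches a brute-force sum and truncation is stable", {
  set.seed(91)
  for (r in 1:10) {
    lam <- runif(1, 0.5, 8)
    x <- rpois(1, lam)
    p <- pois_pmf(lam, 500)
    brute <- sum((cumsum(p) - as.numeric(x <= 0:500))^2)
    expect_equal(score_rps(p, x), brute, tolerance = 1e-10)
    # doubling the support changes nothing beyond 1e-8
    pk <- pois_pmf(lam, qpois(1e-12, lam, lower.tail = FALSE) + 1)
    p2 <- pois_pmf(lam, 2 * length(pk))
    expect_lt(abs(score_rps(pk, x) - score_rps(p2, x)), 1e-8)
    expect_lt(abs(score_quadratic(pk, x) - score_quadratic(p2, x)), 1e-8)
    expect_lt(abs(score_spherical(pk, x) - score_spherical(p2, x)), 1e-8)
  }
  # literal indicator variant differs but stays finite
  p <- pois_pmf(2, 30)
  expect_true(is.finite(score_rps(p, 2, as_printed = TRUE)))
})

test_that("every rule is proper: truth minimizes the expected score", {
  set.seed(92)
  K <- 15
  for (r in 1:5) {
    p <- rgamma(K + 1, 1); p <- p / sum(p)
    expected <- function(q) {
      mu <- sum(0:K * q); sg <- sqrt(sum((0:K - mu)^2 * q))
      sum(vapply(0:K, function(x) {
        p[x + 1] * (score_log(pmax(q, 1e-12), x) + score_quadratic(q, x) +
                      score_spherical(q, x) + score_rps(q, x) +
                      score_dss(mu, max(sg, 1e-6), x))
      }, numeric(1)))
    }
    base <- expected(p)
    # all point masses and a few random competitors
    for (x0 in 0:K) expect_gte(expected(point_mass(x0, K)) + 1e-9, base)
    for (j in 1:5) {
      q <- rgamma(K + 1, 1); q <- q / sum(q)
      expect_gte(expected(q) + 1e-9, base)
    }
  }
})

test_that("mse/mae aggregate correctly and respect Jensen", {
  expect_equal(mse_mae(c(1, 2), c(1, 2)), list(mse = 0, mae = 0))
  expect_equal(mse_mae(c(0, 2), c(1, 1)), list(mse = 1, mae = 1))
  expect_error(mse_mae(1:3, 1:2), "length")
  set.seed(93)
  for (r in 1:10) {
    a <- rpois(20, 5); f <- rpois(20, 5)
    m <- mse_mae(a, f)
    expect_lte(m$mae, sqrt(m$mse) + 1e-12)
  }
  expect_equal(mean_score(c(2, 2, 2)), 2)
  expect_equal(mean_score(5), 5)
})

test_that("forecast scoring averages marginals and reports match", {
  set.seed(94)
  p <- maci_params(c(1, 2), diag(0.2, 2), diag(0.3, 2))
  x <- maci_simulate(p, 120)
  ens <- forecast_obs_driven(p, x, s = 3, R = 2000)
  actual <- matrix(rpois(6, c(1.5, 3)), 3, 2, byrow = TRUE)
  sc <- score_forecast(ens, actual)
  expect_named(sc, c("log", "qs", "sph", "rps", "ds", "se", "mse", "mae"))
  expect_true(all(is.finite(sc)))
  rep2 <- score_report(modelA = sc, modelB = sc)
  expect_equal(rep2[1, -1], rep2[2, -1], ignore_attr = TRUE)
  expect_equal(rep2$model, c("modelA", "modelB"))
})
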