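test_that("log-intensity filtering matches a hand-unrolled recursion", {
  p0 <- loglin_params(c(0, 0), matrix(0, 2, 2), matrix(0, 2, 2))
  x <- count_series(matrix(c(2L, 0L, 1L, 3L), 2, 2))
  f0 <- loglin_filter(p0, x)
  expect_true(all(f0$nu == 0))
  expect_true(all(f0$lambda == 1))

  # zero counts: the +1 offset makes the B term vanish
  pb <- loglin_params(c(0.1, 0.2), matrix(0, 2, 2), matrix(0.5, 2, 2))
  xz <- count_series(matrix(0L, 3, 2))
  fz <- loglin_filter(pb, xz)
  expect_equal(fz$nu[2, ], c(0.1, 0.2), ignore_attr = TRUE)
  expect_equal(fz$nu[3, ], c(0.1, 0.2), ignore_attr = TRUE)

  # two-step manual unroll on a 2x2 example
  p <- loglin_params(c(0.2, -0.1),
                     matrix(c(0.3, 0.1, -0.2, 0.4), 2, 2),
                     matrix(c(0.5, 0.0, 0.2, -0.3), 2, 2))
  x3 <- count_series(matrix(c(2L, 4L, 1L, 0L, 3L, 2L), 3, 2))
  ft <- loglin_filter(p, x3, init = c(0.5, -0.5))
  nu2 <- p$omega + p$A %*% c(0.5, -0.5) + p$B %*% log(c(2, 0) + 1)
  nu3 <- p$omega + p$A %*% nu2 + p$B %*% log(c(4, 3) + 1)
  expect_equal(ft$nu[2, ], as.numeric(nu2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ft$nu[3, ], as.numeric(nu3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # explosive guard names the offending time
  pe <- loglin_params(c(5, 5), diag(2, 2), diag(2, 2))
  expect_error(loglin_filter(pe, x3), "explosive.*t = ")
})

test_that("filtering is equivariant under joint permutation of series", {
  p <- loglin_params(c(0.2, -0.1),
                     matrix(c(0.3, 0.1, -0.2, 0.4), 2, 2),
                     matrix(c(0.5, 0.0, 0.2, -0.3), 2, 2))
  perm <- c(2L, 1L)
  pp <- loglin_params(p$omega[perm], p$A[perm, perm], p$B[perm, perm])
  set.seed(17)
  x <- matrix(rpois(40, 3), 20, 2)
  f1 <- loglin_filter(p, count_series(x), init = c(0.3, -0.2))
  f2 <- loglin_filter(pp, count_series(x[, perm]), init = c(-0.2, 0.3))
  expect_equal(f1$nu, f2$nu[, perm], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("analytic derivatives match finite differences", {
  set.seed(23)
  for (r in 1:3) {
    p <- random_loglin_params()
    x <- loglin_simulate(p, 60)
    init <- log(colMeans(unclass(x)) + 1)
    f <- function(th) loglin_loglik(theta_to_loglin(th), x, init)
    g <- function(th) loglin_score(theta_to_loglin(th), x, init)
    th <- theta_of(p)
    expect_lt(rel_err(loglin_score(p, x, init), fd_grad(f, th)), 1e-6)
    info <- loglin_information(p, x, init)
    Hfd <- -fd_jac(g, th)
    expect_lt(rel_err(info$H, (Hfd + t(Hfd)) / 2), 1e-5)
    expect_gte(min(eigen(info$G, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("stability check reduces to the geometric series for diagonal A, B", {
  # A = 0: condition is just ||B||_2 < 1
  s0 <- loglin_stability(loglin_params(c(0, 0), matrix(0, 2, 2),
                                       diag(0.9, 2)))
  expect_true(s0$stable)
  expect_equal(s0$value, 0.9, tolerance = 1e-10)
  # A = aI, B = bI: sum is b / (1 - a)
  s1 <- loglin_stability(loglin_params(c(0, 0), diag(0.5, 2), diag(0.4, 2)),
                         J = 200)
  expect_equal(s1$value, 0.8, tolerance = 1e-8)
  expect_true(s1$stable)
  s2 <- loglin_stability(loglin_params(c(0, 0), diag(0.5, 2), diag(0.6, 2)),
                         J = 200)
  expect_false(s2$stable)
})

test_that("the catalog log-linear processes simulate without explosion", {
  set.seed(27)
  for (nm in c("LL1", "LL2")) {
    p <- dgp_catalog()[[nm]]$params
    x <- loglin_simulate(p, 500)
    expect_true(all(is.finite(unclass(x))))
    # b21 = 0 and a diagonal: series 2 never responds to series 1
    x2 <- unclass(x); x2[, 1] <- 0L
    f1 <- loglin_filter(p, x)
    f2 <- loglin_filter(p, count_series(x2))
    expect_equal(f1$nu[, 2], f2$nu[, 2], tolerance = 1e-12)
  }
})

test_that("QML finds no dynamics in i.i.d. data and fits simulated data", {
  # on i.i.d. Poisson(1) counts the identified dynamics vanish: omega and B
  # go to zero (A alone is unidentified when B = 0, so it is not checked)
  # and the fitted intensity path is flat at the sample mean
  set.seed(33)
  iid <- count_series(matrix(rpois(2000, 1), 1000, 2))
  fit <- loglin_fit(iid, n_starts = 2)
  expect_lt(max(abs(fit$theta[c("b11", "b21", "b12", "b22")])), 0.15)
  lam <- loglin_filter(fit$params, iid, init = fit$init)$lambda
  expect_lt(max(abs(colMeans(lam[-(1:50), ]) - colMeans(unclass(iid)))), 0.1)

  # diagonal-A restriction pins the off-diagonal feedback at zero
  fd <- loglin_fit(iid, n_starts = 2, diagonal_A = TRUE)
  expect_equal(unname(fd$theta[c("a21", "a12")]), c(0, 0))
  expect_true(all(is.na(fd$se[c("a21", "a12")])))
  expect_false(anyNA(fd$se[c("a11", "a22", "b11")]))

  # simulation and refit at the LL2 truth
  truth <- dgp_catalog()$LL2$params
  set.seed(34)
  x <- loglin_simulate(truth, 2000)
  f2 <- loglin_fit(x)
  named <- c("omega1", "omega2", "a11", "a22", "b11", "b12", "b21", "b22")
  th0 <- theta_of(truth)
  names(th0) <- names(f2$theta)
  expect_true(all(abs(f2$theta[named] - th0[named]) <=
                    3.5 * pmax(f2$se[named], 1e-3)))
})
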