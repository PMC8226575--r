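#' Independent multivariate Poisson pmf
#'
#' Joint probability of a count vector under independent Poisson margins,
#' evaluated in log space.
#'
#' @param x integer vector of non-negative counts.
#' @param lambda positive intensity vector, same length as `x`.
#' @param log if `TRUE` return the log probability.
#' @return Scalar (log-)probability.
#' @export
dpois_indep <- function(x, lambda, log = FALSE) {
  check_counts(x)
  if (any(lambda <= 0)) stop("intensities must be > 0")
  lp <- sum(stats::dpois(x, lambda, log = TRUE))
  if (log) lp else exp(lp)
}

check_counts <- function(x) {
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  invisible(x)
}

#' Common-shock (trivariate reduction) specification
#'
#' Dependent Poisson counts built as `X_i = Y_i + Y_0` with independent
#' `Y_i ~ Poisson(lambda_i)` and a shared shock `Y_0 ~ Poisson(lambda0)`.
#' The shock intensity equals the common covariance of every pair; marginals
#' are `Poisson(lambda_i + lambda0)`. Dependence is necessarily positive.
#'
#' @param lambda base intensities (`> 0`), length `n >= 2`.
#' @param lambda0 shared shock intensity (`>= 0`); `0` recovers independence.
#' @return An object of class `common_shock`.
#' @export
common_shock <- function(lambda, lambda0 = 0) {
  if (any(lambda <= 0)) stop("base intensities must be > 0")
  if (length(lambda) < 2L) stop("need at least two series")
  if (lambda0 < 0) stop("shock intensity must be >= 0")
  structure(list(lambda = as.numeric(lambda), lambda0 = as.numeric(lambda0)),
            class = "common_shock")
}

#' Common-shock multivariate Poisson pmf
#'
#' Evaluates the joint pmf of the common-shock construction as the finite
#' convolution over the shared component,
#' `sum_k Pois(k; lambda0) prod_j Pois(x_j - k; lambda_j)`, `k = 0..min(x)`,
#' accumulated in log space. For two series this is algebraically identical
#' to the classical trivariate-reduction pmf.
#'
#' @param x integer count vector, length matching `spec$lambda`.
#' @param spec a [common_shock] specification.
#' @param log if `TRUE` return the log probability.
#' @return Scalar (log-)probability.
#' @export
dpois_common_shock <- function(x, spec, log = FALSE) {
  stopifnot(inherits(spec, "common_shock"))
  check_counts(x)
  if (length(x) != length(spec$lambda))
    stop("length(x) must match the number of base intensities")
  if (spec$lambda0 == 0) {
    lp <- sum(stats::dpois(x, spec$lambda, log = TRUE))
  } else {
    m <- min(x)
    k <- 0:m
    terms <- stats::dpois(k, spec$lambda0, log = TRUE)
    for (j in seq_along(x))
      terms <- terms + stats::dpois(x[j] - k, spec$lambda[j], log = TRUE)
    mx <- max(terms)
    lp <- mx + base::log(sum(exp(terms - mx)))
  }
  if (log) lp else exp(lp)
}

#' Sample from the common-shock construction
#'
#' @param n number of draws.
#' @param spec a [common_shock] specification.
#' @return `n x length(lambda)` integer matrix of counts.
#' @export
rpois_common_shock <- function(n, spec) {
  stopifnot(inherits(spec, "common_shock"))
  p <- length(spec$lambda)
  y <- vapply(spec$lambda, function(l) stats::rpois(n, l), integer(n))
  if (n == 1L) y <- matrix(y, nrow = 1L)
  y0 <- stats::rpois(n, spec$lambda0)
  y + y0
}

#' Pairwise-shock specification
#'
#' Richer covariance structure than the single common shock: each pair
#' `(i, j)` gets its own shared Poisson component, `Y_i = X_i + sum_{j != i}
#' X_{ij}` with `X_ij ~ Poisson(lambda_ij)` shared between series `i` and
#' `j`. Covariance of series `i` and `j` equals `lambda_ij`; marginals are
#' Poisson with rate `lambda_i + sum_{j != i} lambda_ij`.
#'
#' @param lambda individual intensities, length `n >= 2`.
#' @param lambda_pair symmetric `n x n` matrix of pairwise shock intensities
#'   (diagonal ignored), or for `n = 3` a vector `c(l12, l13, l23)`.
#' @return An object of class `pairwise_shock`.
#' @export
pairwise_shock <- function(lambda, lambda_pair) {
  n <- length(lambda)
  if (n < 2L) stop("need at least two series")
  if (any(lambda < 0)) stop("intensities must be >= 0")
  if (!is.matrix(lambda_pair)) {
    if (n != 3L || length(lambda_pair) != 3L)
      stop("vector form of 'lambda_pair' is c(l12, l13, l23) for n = 3")
    m <- matrix(0, 3L, 3L)
    m[1L, 2L] <- m[2L, 1L] <- lambda_pair[1L]
    m[1L, 3L] <- m[3L, 1L] <- lambda_pair[2L]
    m[2L, 3L] <- m[3L, 2L] <- lambda_pair[3L]
    lambda_pair <- m
  }
  if (!isSymmetric(unname(lambda_pair)) || any(lambda_pair < 0))
    stop("'lambda_pair' must be symmetric with non-negative entries")
  diag(lambda_pair) <- 0
  structure(list(lambda = as.numeric(lambda), lambda_pair = lambda_pair),
            class = "pairwise_shock")
}

#' Moments of the pairwise-shock construction
#'
#' @param spec a [pairwise_shock] specification.
#' @return List with `mean` (vector `lambda_i + sum_j lambda_ij`) and `cov`
#'   (matrix with that mean on the diagonal and `lambda_ij` off-diagonal).
#' @export
pairwise_shock_moments <- function(spec) {
  stopifnot(inherits(spec, "pairwise_shock"))
  mu <- spec$lambda + rowSums(spec$lambda_pair)
  v <- spec$lambda_pair
  diag(v) <- mu
  list(mean = mu, cov = v)
}

#' Sample from the pairwise-shock construction
#'
#' @param n number of draws.
#' @param spec a [pairwise_shock] specification.
#' @return `n x length(lambda)` integer matrix of counts.
#' @export
rpois_pairwise_shock <- function(n, spec) {
  stopifnot(inherits(spec, "pairwise_shock"))
  p <- length(spec$lambda)
  out <- vapply(spec$lambda, function(l) stats::rpois(n, l), integer(n))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      lij <- spec$lambda_pair[i, j]
      if (lij > 0) {
        shared <- stats::rpois(n, lij)
        out[, i] <- out[, i] + shared
        out[, j] <- out[, j] + shared
      }
    }
  }
  out
}

# Component-wise truncation point with tail mass below `tail` for the
# marginal Poisson of each series (used by normalization checks).
poisson_support_cap <- function(lambda, tail = 1e-12) {
  stats::qpois(tail, lambda, lower.tail = FALSE) + 1L
}
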