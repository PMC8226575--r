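#' Scoring rules for count forecasts
#'
#' Proper scoring rules evaluating a discrete predictive distribution `p`
#' (a probability vector over the support `0..K`, as produced by
#' [predictive_pmf()]) against a realized count `x`. All rules are
#' negatively oriented: smaller is better.
#'
#' * logarithmic score: `-log p_x`
#' * quadratic (Brier) score: `-2 p_x + ||p||^2`
#' * spherical score: `-p_x / ||p||`, with `||p||^2 = sum_k p_k^2`
#' * ranked probability score: `sum_k (P_k - 1(x <= k))^2` over the
#'   cumulative `P_k` (set `as_printed = TRUE` for the `1(x >= k)`
#'   indicator variant)
#' * squared error score: `(x - mu_p)^2` with `mu_p` the predictive mean
#' * Dawid-Sebastiani score: `((x - mu)/sigma)^2 + 2 log sigma`
#'   (`as_printed = TRUE` drops the square on the standardized residual)
#'
#' Supports are truncated; the tail mass beyond `K` contributes less than
#' the marginal tail probability to every rule, so a support capturing all
#' but `1e-9` of the mass leaves the scores stable to well below `1e-8`.
#'
#' @param p predictive probability vector over `0..(length(p) - 1)`.
#' @param x realized count.
#' @param mu,sigma predictive mean and standard deviation (`sigma > 0`).
#' @param as_printed use the literal textbook-variant orientation (see
#'   above) instead of the standard proper form.
#' @return Scalar score.
#' @name scoring-rules
NULL

check_pmf <- function(p, x) {
  if (any(p < 0)) stop("'p' must be non-negative")
  if (x < 0 || x != round(x)) stop("'x' must be a non-negative count")
  invisible(p)
}

pmf_at <- function(p, x) if (x + 1L <= length(p)) p[x + 1L] else 0

#' @rdname scoring-rules
#' @export
score_log <- function(p, x) {
  check_pmf(p, x)
  px <- pmf_at(p, x)
  if (px == 0) {
    warning("outcome has zero predictive probability; log score is Inf")
    return(Inf)
  }
  -log(px)
}

#' @rdname scoring-rules
#' @export
score_quadratic <- function(p, x) {
  check_pmf(p, x)
  -2 * pmf_at(p, x) + sum(p^2)
}

#' @rdname scoring-rules
#' @export
score_spherical <- function(p, x) {
  check_pmf(p, x)
  -pmf_at(p, x) / sqrt(sum(p^2))
}

#' @rdname scoring-rules
#' @export
score_rps <- function(p, x, as_printed = FALSE) {
  check_pmf(p, x)
  k <- seq_along(p) - 1L
  P <- cumsum(p)
  ind <- if (as_printed) as.numeric(x >= k) else as.numeric(x <= k)
  sum((P - ind)^2)
}

#' @rdname scoring-rules
#' @export
score_ses <- function(p, x) {
  check_pmf(p, x)
  mu <- sum((seq_along(p) - 1L) * p) / sum(p)
  (x - mu)^2
}

#' @rdname scoring-rules
#' @export
score_dss <- function(mu, sigma, x, as_printed = FALSE) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  z <- (x - mu) / sigma
  if (as_printed) z + 2 * log(sigma) else z^2 + 2 * log(sigma)
}

#' Mean squared and mean absolute error of point forecasts
#'
#' @param actuals realized counts.
#' @param forecasts point forecasts (same length).
#' @return List with `mse` and `mae`.
#' @export
mse_mae <- function(actuals, forecasts) {
  if (length(actuals) != length(forecasts))
    stop("'actuals' and 'forecasts' must have the same length")
  e <- actuals - forecasts
  list(mse = mean(e^2), mae = mean(abs(e)))
}

#' Mean score over an evaluation set
#'
#' @param scores numeric vector of per-observation scores.
#' @return Their arithmetic mean.
#' @export
mean_score <- function(scores) mean(scores)

#' Score a predictive ensemble against realized counts
#'
#' Evaluates all six rules on the per-horizon, per-series marginal
#' predictive distributions and averages over the evaluation set: for
#' each `(horizon, series)` pair the marginal pmf is formed with
#' [predictive_pmf()] (support extended to cover the realized count), the
#' distribution-based rules are computed from it, and the squared/absolute
#' errors use the predictive mean as point forecast.
#'
#' @param ens a [predictive_ensemble] with `s` horizons and `n` series.
#' @param actuals realized counts, an `s x n` matrix (or [count_series]).
#' @param dss_as_printed,rps_as_printed literal-variant flags, see
#'   [scoring-rules].
#' @return Named numeric vector with components `log`, `qs`, `sph`,
#'   `rps`, `ds`, `se`, `mse`, `mae` (the first six are mean scores).
#' @export
score_forecast <- function(ens, actuals, dss_as_printed = FALSE,
                           rps_as_printed = FALSE) {
  stopifnot(inherits(ens, "predictive_ensemble"))
  A <- as.matrix(actuals)
  if (nrow(A) != ens$s || ncol(A) != ens$n)
    stop("'actuals' must be an s x n matrix matching the ensemble")
  cells <- expand.grid(h = seq_len(ens$s), i = seq_len(ens$n))
  per <- matrix(NA_real_, nrow(cells), 6L,
                dimnames = list(NULL, c("log", "qs", "sph", "rps", "ds",
                                        "se")))
  pmean <- matrix(NA_real_, ens$s, ens$n)
  for (r in seq_len(nrow(cells))) {
    h <- cells$h[r]; i <- cells$i[r]
    x <- A[h, i]
    p <- predictive_pmf(ens, h, i, support = x)
    mu <- sum((seq_along(p) - 1L) * p) / sum(p)
    sg <- sqrt(max(sum(((seq_along(p) - 1L) - mu)^2 * p) / sum(p), 1e-12))
    pmean[h, i] <- mu
    per[r, ] <- c(score_log(p, x), score_quadratic(p, x),
                  score_spherical(p, x), score_rps(p, x, rps_as_printed),
                  score_dss(mu, sg, x, dss_as_printed), score_ses(p, x))
  }
  mm <- mse_mae(as.numeric(A), as.numeric(pmean))
  c(colMeans(per), mse = mm$mse, mae = mm$mae)
}

#' Assemble a score report across models
#'
#' @param ... named [score_forecast()] result vectors (or a single named
#'   list of them), one per model.
#' @return Data frame with one row per model and one column per measure;
#'   every column is negatively oriented (lower is better).
#' @export
score_report <- function(...) {
  rows <- list(...)
  if (length(rows) == 1L && is.list(rows[[1L]]) &&
      !is.numeric(rows[[1L]])) rows <- rows[[1L]]
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("each model's scores must be named")
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  cbind(data.frame(model = names(rows)), out, row.names = NULL)
}
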