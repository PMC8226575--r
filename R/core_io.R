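#' Multivariate count series container
#'
#' Wraps a `T x n` integer matrix of counts (one row per time point, one
#' column per series) with unique series labels. All model code in the
#' package consumes and produces this class.
#'
#' @param values integer matrix (or something coercible) of non-negative
#'   counts, `T x n`.
#' @param labels optional character vector of `n` unique series names;
#'   defaults to existing column names or `x1, x2, ...`.
#' @return An object of class `count_series`: the integer matrix with
#'   column names set, carrying its time index as row order.
#' @examples
#' y <- count_series(cbind(rpois(10, 2), rpois(10, 5)))
#' summarize_counts(y)
#' @export
count_series <- function(values, labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must be a T x n matrix with T >= 1, n >= 1")
  if (any(!is.finite(values)))
    stop("counts must be finite; missing values are not supported")
  if (any(values < 0))
    stop("counts must be non-negative")
  if (any(values != round(values)))
    stop("counts must be integers")
  storage.mode(values) <- "integer"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("x", seq_len(ncol(values)))
  }
  if (length(labels) != ncol(values) || anyDuplicated(labels))
    stop("'labels' must be ", ncol(values), " unique names")
  colnames(values) <- labels
  rownames(values) <- NULL
  structure(values, class = c("count_series", "matrix", "array"))
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series: T = %d, n = %d [%s]>\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_series")) return(structure(unclass(x), class = NULL))
  count_series(x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' Read a count series from CSV
#'
#' Expects a comma-separated UTF-8 file with one header row of series labels
#' and a body of non-negative integer cells. An optional first column named
#' `t` is treated as the time index and dropped (row order is the index).
#'
#' @param path path to an existing CSV file.
#' @return A [count_series].
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("empty or unreadable count CSV: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty count CSV: ", path)
  if (names(df)[1L] == "t") df <- df[, -1L, drop = FALSE]
  m <- as.matrix(df)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count at row %d, column '%s': cells must be non-negative integers",
                 bad[1L, 1L], colnames(m)[bad[1L, 2L]]))
  count_series(m, labels = colnames(m))
}

#' Write a count series to CSV
#'
#' Inverse of [read_counts_csv()]: round-tripping is the identity.
#'
#' @param x a [count_series] (or count matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(x, path) {
  x <- count_series(x)
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-series descriptive statistics
#'
#' @param x a [count_series] or count matrix.
#' @return A data frame with one row per series: `series`, `mean`, `median`,
#'   `sd`, `min`, `max` (all in count units).
#' @export
summarize_counts <- function(x) {
  x <- count_series(x)
  m <- unclass(x)
  data.frame(
    series = colnames(m),
    mean = apply(m, 2L, mean),
    median = apply(m, 2L, stats::median),
    sd = apply(m, 2L, stats::sd),
    min = apply(m, 2L, min),
    max = apply(m, 2L, max),
    row.names = NULL
  )
}

#' Read a run configuration file
#'
#' Configuration files are YAML or JSON with (a subset of) the keys
#' `model`, `params`, `priors`, `seed`, `estimation` (particles `N`,
#' iterations `M`, `warmup`) and `forecast` (horizon `s`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    # keep single-letter keys like "N" as strings instead of YAML 1.1 bools
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
      "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE))
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON, got .", ext)
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
      stop("config 'seed' must be an integer")
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "run_config")
}

# Deterministic child seeds from a root seed (kept below 2^31).
spawn_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

# Two sub-2^31 doubles drawn from R's RNG stream, used to seed the internal
# C++ generator so that set.seed() controls all compiled randomness.
cpp_seed_pair <- function() {
  floor(stats::runif(2L) * 2147483647)
}
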