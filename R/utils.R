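#' @importFrom rlang abort warn .data
#' @importFrom data.table :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm runif rbinom rbeta rgeom pnorm pt cor quantile median p.adjust
#' @importFrom utils head combn
NULL

# Run `expr` under a fixed RNG seed when one is supplied, leaving the caller's
# RNG state untouched; with seed = NULL the global stream is used as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1)
    withr::with_seed(as.integer(seed), expr)
  }
}

#' Nearest-rank-lower quantile
#'
#' The single quantile convention used throughout the package (null-distribution
#' thresholds, coverage percentiles): the value at sorted rank
#' `max(1, floor(n * p / 100))`. Declared once so that thresholds are exact and
#' testable rather than interpolation-dependent.
#'
#' @param x Numeric vector (NAs dropped).
#' @param p Percentile in `[0, 100]`.
#' @return A single number.
#' @examples
#' quantile_nearest_lower(1:100, 5) # 5
#' @export
quantile_nearest_lower <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) abort("quantile_nearest_lower(): no non-missing values")
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 100) {
    abort("`p` must be a single percentile in [0, 100]")
  }
  x[max(1L, floor(n * p / 100))]
}

# 0-based half-open window index of a position for window width `w`
window_index <- function(position, w) as.integer(position %/% w)

# Tiling of [0, genome_length) into windows of width `w`; last window may be short
genome_windows <- function(genome_length, w) {
  if (w <= 0) abort("window size must be positive")
  starts <- seq(0L, genome_length - 1L, by = w)
  tibble(
    window_index = seq_along(starts) - 1L,
    window_start = as.integer(starts),
    window_end = as.integer(pmin(starts + w, genome_length))
  )
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  x
}
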