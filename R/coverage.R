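#' Per-window mean fold-coverage of a read set
#'
#' Per-base coverage (every base a read spans counts) averaged within tiling
#' windows of `window` bases; the last window may be short.
#'
#' @param reads A read set (or tibble with `start`, `length`).
#' @param genome_length Genome length in bases (defaults to the read set's
#'   attribute).
#' @param window Window width in bases (default 10,000).
#' @return A tibble of class `"coverage_track"` with columns `window_index`,
#'   `window_start`, `window_end`, `coverage`.
#' @export
coverage_track <- function(reads, genome_length = NULL, window = 10000L) {
  glen <- genome_length %||% attr(reads, "genome_length")
  if (is.null(glen)) abort("genome_length is required")
  depth_delta <- numeric(glen + 1L)
  if (nrow(reads) > 0) {
    add <- tapply(rep(1L, nrow(reads)), reads$start, sum)
    depth_delta[as.integer(names(add)) + 1L] <-
      depth_delta[as.integer(names(add)) + 1L] + add
    ends <- pmin(reads$start + reads$length, glen)
    sub <- tapply(rep(1L, nrow(reads)), ends, sum)
    depth_delta[as.integer(names(sub)) + 1L] <-
      depth_delta[as.integer(names(sub)) + 1L] - sub
  }
  depth <- cumsum(depth_delta[seq_len(glen)])
  win <- genome_windows(glen, window)
  cov <- vapply(seq_len(nrow(win)), function(i) {
    mean(depth[(win$window_start[i] + 1L):win$window_end[i]])
  }, numeric(1))
  out <- mutate(win, coverage = cov)
  structure(out, window_size = as.integer(window),
            class = c("coverage_track", class(tibble())))
}

#' Coverage-standardization target from pooled tracks
#'
#' The target fold coverage for subsampling: a low percentile (default the
#' 5th) of the pooled per-window coverage values over all supplied samples, so
#' that after subsampling essentially every window in every sample can reach
#' the target. Samples with systematically different depth (e.g. a late
#' stationary-phase time point) can be pooled separately via `groups`.
#'
#' @param tracks A [coverage_track()] or list of them.
#' @param percentile Percentile in `[0, 100]` (default 5), taken with the
#'   package-wide nearest-rank-lower rule.
#' @param groups Optional vector (one label per track): percentiles are then
#'   computed within each group and returned as a named vector.
#' @return A single fold-coverage value, or a named vector when `groups` is
#'   given.
#' @export
target_coverage <- function(tracks, percentile = 5, groups = NULL) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (length(tracks) == 0) abort("`tracks` must contain at least one coverage track")
  if (is.null(groups)) {
    vals <- unlist(purrr::map(tracks, "coverage"))
    quantile_nearest_lower(vals, percentile)
  } else {
    if (length(groups) != length(tracks)) {
      abort("`groups` must have one label per track")
    }
    vapply(split(tracks, groups), function(tr) {
      quantile_nearest_lower(unlist(purrr::map(tr, "coverage")), percentile)
    }, numeric(1))
  }
}

#' Reads to sample from a window for a coverage target
#'
#' `round(target * window / mean_read_length)`: e.g. a 100-fold target with
#' 2-Kbp reads needs 500 reads originating within a 10-Kbp window.
#'
#' @param target Target fold coverage (≥ 0).
#' @param window Window width in bases (> 0).
#' @param mean_read_length Mean read length in bases (> 0).
#' @return An integer read count.
#' @examples
#' reads_per_window(100, 10000, 2000) # 500
#' @export
reads_per_window <- function(target, window, mean_read_length) {
  if (!is.numeric(target) || target < 0) abort("`target` must be non-negative")
  if (!is.numeric(window) || window <= 0) abort("`window` must be positive")
  if (!is.numeric(mean_read_length) || mean_read_length <= 0) {
    abort("`mean_read_length` must be positive")
  }
  as.integer(round(target * window / mean_read_length))
}

#' Standardize coverage by windowed read subsampling
#'
#' Implements the coverage-standardization loop: compute the pool's mean read
#' length, draw `reads_per_window(target, window, mean_length)` reads
#' originating within each window (start coordinate in the window, without
#' replacement; short final windows get proportionally fewer), then measure
#' the realized per-window coverage. If the median relative error exceeds
#' `tol` — typically because of irregularities in the read-length
#' distribution — the mean read length is re-estimated from the mapped
#' subsample and the draw repeated, up to `max_iter` times; the iterate with
#' the smallest median relative error is returned.
#'
#' @param reads A read set whose overall coverage is at least `target`.
#' @param target Target fold coverage.
#' @param genome_length Genome length (defaults to the read set's attribute).
#' @param window Window width in bases (default 10,000).
#' @param tol Acceptable median relative coverage error (default 0.1).
#' @param max_iter Maximum resampling iterations (default 5).
#' @param seed Integer seed.
#' @return A list with `reads` (the subsampled read set) and `plan`
#'   (class `"subsample_plan"`: target, final mean read length, per-window
#'   draw counts, iterations used, median relative error, shortfall windows).
#' @export
subsample <- function(reads, target, genome_length = NULL, window = 10000L,
                      tol = 0.1, max_iter = 5L, seed = NULL) {
  glen <- genome_length %||% attr(reads, "genome_length")
  if (is.null(glen)) abort("genome_length is required")
  overall <- sum(as.numeric(reads$length)) / glen
  if (overall < target) {
    abort(sprintf("pool coverage (%.1fx) is below the target (%.1fx)",
                  overall, target))
  }
  win <- genome_windows(glen, window)
  widx <- window_index(reads$start, window)
  by_window <- split(seq_len(nrow(reads)), factor(widx, levels = win$window_index))

  with_seed_if(seed, {
    mrl <- mean(reads$length)
    best <- NULL
    iterations <- 0L
    for (it in seq_len(max_iter)) {
      iterations <- it
      widths <- win$window_end - win$window_start
      n_want <- as.integer(round(target * widths / mrl))
      shortfall <- integer(0)
      picked <- unlist(purrr::map(seq_len(nrow(win)), function(i) {
        avail <- by_window[[i]]
        k <- n_want[i]
        if (length(avail) <= k) {
          if (length(avail) < k) shortfall <<- c(shortfall, win$window_index[i])
          avail
        } else {
          avail[sample.int(length(avail), k)]
        }
      }))
      cand <- subset_read_set(reads, sort(picked))
      realized <- coverage_track(cand, glen, window)$coverage
      err <- median(abs(realized - target) / target)
      if (is.null(best) || err < best$err) {
        best <- list(reads = cand, err = err, n_want = n_want, mrl = mrl,
                     shortfall = shortfall, iteration = it)
      }
      if (err <= tol) break
      mrl <- mean(cand$length)  # re-estimate from the mapped subsample
    }
    if (best$err > tol) {
      warn(sprintf(
        "subsample: median relative coverage error %.3f above tol %.3f after %d iteration(s)",
        best$err, tol, iterations))
    }
    if (length(best$shortfall) > 0) {
      warn(sprintf("subsample: %d window(s) had fewer originating reads than requested",
                   length(best$shortfall)))
    }
    plan <- structure(
      list(target_coverage = target,
           mean_read_length = best$mrl,
           reads_per_window = tibble(window_index = win$window_index,
                                     window_start = win$window_start,
                                     n_requested = best$n_want),
           iterations_used = iterations,
           median_rel_error = best$err,
           shortfall_windows = best$shortfall),
      class = "subsample_plan"
    )
    list(reads = best$reads, plan = plan)
  })
}

#' @export
print.subsample_plan <- function(x, ...) {
  cat(sprintf(
    "<subsample_plan: target %.1fx, mean read length %.0f bp, %d iteration(s), median rel. error %.3f>\n",
    x$target_coverage, x$mean_read_length, x$iterations_used,
    x$median_rel_error))
  invisible(x)
}

#' Write a realized-coverage track as a BEDGRAPH-style TSV
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @param contig_id Contig name.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, path, contig_id = "contig_1") {
  bed <- data.frame(chrom = contig_id, start = track$window_start,
                    end = track$window_end, value = track$coverage)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
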