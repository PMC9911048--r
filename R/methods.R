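#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an empirical null distribution
#'
#' @param x A [build_null()] result.
#' @param ... Unused.
#' @return One row per null site with its p-value; `glance()` gives the
#'   one-row summary (site count, threshold, percentile).
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(null_rank = seq_along(x$pvalues), pvalue = sort(x$pvalues))
}

#' @rdname tidy.null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(n_sites = length(x$pvalues),
         threshold = x$threshold,
         threshold_percentile = x$threshold_percentile,
         region_start = x$region[1], region_end = x$region[2],
         frac_below_threshold = mean(x$pvalues < x$threshold))
}

#' Tidy a subsampling plan
#'
#' @param x A `subsample_plan` from [subsample()].
#' @param ... Unused.
#' @return `tidy()` gives per-window requested read counts; `glance()` the
#'   one-row run summary.
#' @export
tidy.subsample_plan <- function(x, ...) x$reads_per_window

#' @rdname tidy.subsample_plan
#' @export
glance.subsample_plan <- function(x, ...) {
  tibble(target_coverage = x$target_coverage,
         mean_read_length = x$mean_read_length,
         iterations_used = x$iterations_used,
         median_rel_error = x$median_rel_error,
         n_shortfall_windows = length(x$shortfall_windows))
}

#' Summaries of site calls
#'
#' @param x A [classify_sites()] tibble.
#' @param ... Unused.
#' @return `glance()` gives per-motif site counts, methylated fraction and the
#'   threshold used.
#' @export
glance.site_calls <- function(x, ...) {
  out <- as_tibble(x) %>%
    group_by(.data$condition, .data$motif) %>%
    summarise(n_sites = n(),
              n_methylated = sum(.data$methylated),
              methylated_fraction = mean(.data$methylated),
              .groups = "drop")
  out$threshold <- attr(x, "threshold")
  out
}

#' Genome-wide summary of a window profile
#'
#' @param x A [window_fractions()] tibble.
#' @param ... Unused.
#' @return One row per condition × motif: window counts, the genome-wide
#'   methylated fraction (weighted, i.e. total methylated / total sites) and
#'   the unweighted mean window fraction.
#' @export
glance.window_profile <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$condition, .data$motif) %>%
    summarise(n_windows = n(),
              n_sites = sum(.data$n_sites),
              n_methylated = sum(.data$n_methylated),
              genome_fraction = sum(.data$n_methylated) / sum(.data$n_sites),
              mean_window_fraction = mean(.data$fraction),
              .groups = "drop")
}
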