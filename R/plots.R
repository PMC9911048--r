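#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_tile geom_col geom_histogram geom_vline facet_wrap labs
#'   scale_y_log10 scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a titration summary
#'
#' Median site p-value (with interquartile ribbon) against the native-read
#' fraction, per motif, on a log p scale — sensitivity rising with the
#' methylated-molecule fraction appears as a falling curve, steeper for 5mC
#' (Dcm) than 6mA (Dam).
#'
#' @param object A [summarize_titration()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$fraction_native, y = .data$p_median,
                     colour = .data$motif, fill = .data$motif)) +
    geom_ribbon(aes(ymin = .data$p_q25, ymax = .data$p_q75), alpha = 0.2,
                colour = NA) +
    geom_line() +
    geom_point() +
    scale_y_log10() +
    labs(x = "fraction of native reads", y = "site p-value (median, IQR)",
         colour = "motif", fill = "motif") +
    theme_minimal()
}

#' Plot a window methylation-fraction profile along the genome
#'
#' @param object A [window_fractions()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$window_start / 1e6, y = .data$fraction,
                     colour = .data$condition)) +
    geom_line(alpha = 0.8) +
    facet_wrap(~motif, ncol = 1) +
    labs(x = "genome position (Mbp)", y = "methylated fraction of motif sites",
         colour = "condition") +
    theme_minimal()
}

#' Plot a null p-value distribution and its threshold
#'
#' @param object A [build_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$pvalue)) +
    geom_histogram(bins = 30, boundary = 0) +
    geom_vline(xintercept = object$threshold, linetype = 2) +
    labs(x = "null site p-value", y = "count",
         title = sprintf("empirical null (threshold %.3g at %gth percentile)",
                         object$threshold, object$threshold_percentile)) +
    theme_minimal()
}

#' Heatmap of the pairwise condition correlation matrix
#'
#' @param object A [pairwise_condition_matrix()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_matrix <- function(object, ...) {
  both <- bind_rows(
    object,
    dplyr::rename(object, condition_a = "condition_b",
                  condition_b = "condition_a")
  )
  ggplot(both, aes(x = .data$condition_a, y = .data$condition_b,
                   fill = .data$r)) +
    geom_tile() +
    facet_wrap(~motif) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "partial r") +
    theme_minimal()
}

#' Heatmap of the long-range correlation scan
#'
#' @param object A [long_range_scan()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.long_range_grid <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$separation),
                     y = factor(.data$window_size), fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "separation (bp)", y = "window size (bp)", fill = "r") +
    theme_minimal()
}
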