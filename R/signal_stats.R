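# ---- Mann-Whitney U internals -------------------------------------------
#
# The two-sided U p-value is the workhorse of the whole pipeline, so the
# conventions are pinned down here once:
#   * midranks for ties;
#   * exact enumeration over all C(n1+n2, n1) label assignments when both
#     groups have at most `exact_max` observations (the null is symmetric
#     around n1*n2/2 even under ties, because swapping labels maps U to
#     n1*n2 - U);
#   * otherwise a tie-corrected normal approximation with a 0.5 continuity
#     correction.

exact_max_default <- 8L

# exact two-sided p by enumeration of rank assignments (handles ties via
# midranks); x is "native", y is "wga"
u_exact_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  picks <- combn(N, n1)
  u_all <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-corrected normal approximation with continuity correction; vectorised.
# tie_term = sum over distinct values of (t^3 - t) within the pooled sample.
u_normal_pvalue <- function(u, n1, n2, tie_term) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  s2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- pmax(0, abs(u - mu) - 0.5) / sqrt(s2)
  p <- 2 * pnorm(-z)
  p[!is.finite(z)] <- 1  # all observations tied: no evidence either way
  pmin(1, p)
}

# Welch two-sample two-sided p; vectorised over positions. Zero-variance
# convention: both groups constant and equal -> 1; constant and unequal ->
# machine epsilon (a guarded "p -> 0").
welch_pvalue <- function(m1, m2, v1, v2, n1, n2) {
  p <- rep(NA_real_, length(m1))
  small <- n1 < 2 | n2 < 2
  se2 <- v1 / n1 + v2 / n2
  zerovar <- !small & se2 == 0
  p[zerovar & m1 == m2] <- 1
  p[zerovar & m1 != m2] <- .Machine$double.eps
  ok <- !small & se2 > 0
  if (any(ok)) {
    tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 /
      ((v1[ok] / n1[ok])^2 / (n1[ok] - 1) + (v2[ok] / n2[ok])^2 / (n2[ok] - 1))
    p[ok] <- 2 * pt(-abs(tstat), df)
  }
  p
}

#' Two-sample signal test at a single position
#'
#' Compares native and WGA signal observations at one genomic position:
#' a two-sided Mann-Whitney U test (midranks, tie-corrected normal
#' approximation with continuity correction; exact enumeration when both
#' samples have at most 8 observations), a Welch two-sided t test, and the
#' mean signal difference.
#'
#' @param native_signals,wga_signals Non-empty numeric vectors.
#' @return A list with `u_pvalue`, `t_pvalue`, `mean_diff`
#'   (= `mean(native) - mean(wga)`).
#' @examples
#' position_test(c(10.1, 10.2, 10.3), c(11.1, 11.2, 11.4))$u_pvalue # 0.1
#' @export
position_test <- function(native_signals, wga_signals) {
  if (length(native_signals) == 0 || length(wga_signals) == 0) {
    abort("both samples need at least one observation (coverage error)")
  }
  n1 <- length(native_signals); n2 <- length(wga_signals)
  if (max(n1, n2) <= exact_max_default) {
    u_p <- u_exact_pvalue(native_signals, wga_signals)
  } else {
    pooled <- c(native_signals, wga_signals)
    r <- rank(pooled)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    t_counts <- table(pooled)
    u_p <- u_normal_pvalue(u, n1, n2, sum(t_counts^3 - t_counts))
  }
  m1 <- mean(native_signals); m2 <- mean(wga_signals)
  t_p <- welch_pvalue(m1, m2,
                      stats::var(native_signals), stats::var(wga_signals),
                      n1, n2)
  list(u_pvalue = u_p, t_pvalue = t_p, mean_diff = m1 - m2)
}

#' Per-position native-vs-WGA difference table
#'
#' Merges two event tables into one record per genomic position carrying both
#' coverages, the mean signal difference and the U- and t-test p-values —
#' the same column semantics as a Nanodisco merged difference file, so
#' converted Nanodisco tables can be analysed downstream identically.
#' Positions where either sample has fewer than `min_cov` observations are
#' dropped.
#'
#' @param native,wga Event tables (see [simulate_signals()] /
#'   [read_event_table_tsv()]).
#' @param min_cov Minimum observations per sample at a position (default 5).
#' @return A tibble of class `"difference_table"` with columns `position`,
#'   `cov_native`, `cov_wga`, `mean_diff`, `u_pvalue`, `t_pvalue`, sorted by
#'   position.
#' @export
difference_table <- function(native, wga, min_cov = 5L) {
  for (nm in c("position", "signal")) {
    if (!nm %in% names(native) || !nm %in% names(wga)) {
      abort(sprintf("event tables need a `%s` column", nm))
    }
  }
  if (nrow(native) == 0 || nrow(wga) == 0 ||
      length(intersect(unique(native$position), unique(wga$position))) == 0) {
    warn("native and wga event tables cover disjoint position ranges")
    return(structure(
      tibble(position = integer(), cov_native = integer(),
             cov_wga = integer(), mean_diff = double(),
             u_pvalue = double(), t_pvalue = double()),
      class = c("difference_table", class(tibble()))))
  }

  dt <- data.table::rbindlist(list(
    data.table::data.table(position = native$position, signal = native$signal,
                           grp = 1L),
    data.table::data.table(position = wga$position, signal = wga$signal,
                           grp = 2L)
  ))
  cnt <- dt[, list(n1 = sum(grp == 1L), n2 = sum(grp == 2L)), by = "position"]
  keep <- cnt[cnt$n1 >= min_cov & cnt$n2 >= min_cov, ]
  if (nrow(keep) == 0) {
    warn("no position reaches min_cov in both samples")
    return(structure(
      tibble(position = integer(), cov_native = integer(),
             cov_wga = integer(), mean_diff = double(),
             u_pvalue = double(), t_pvalue = double()),
      class = c("difference_table", class(tibble()))))
  }
  dt <- dt[dt$position %in% keep$position, ]
  data.table::setorderv(dt, "position")

  dt[, `:=`(r = data.table::frank(signal, ties.method = "average")),
     by = "position"]
  stats_tbl <- dt[, list(
    n1 = sum(grp == 1L), n2 = sum(grp == 2L),
    rsum1 = sum(r[grp == 1L]),
    m1 = mean(signal[grp == 1L]), m2 = mean(signal[grp == 2L]),
    v1 = stats::var(signal[grp == 1L]), v2 = stats::var(signal[grp == 2L])
  ), by = "position"]
  ties <- dt[, list(n = .N), by = c("position", "signal")][
    , list(tie_term = sum(n^3 - n)), by = "position"]
  stats_tbl <- merge(stats_tbl, ties, by = "position")

  u <- stats_tbl$rsum1 - stats_tbl$n1 * (stats_tbl$n1 + 1) / 2
  u_p <- u_normal_pvalue(u, stats_tbl$n1, stats_tbl$n2, stats_tbl$tie_term)

  # exact enumeration where both samples are small
  ex <- which(pmax(stats_tbl$n1, stats_tbl$n2) <= exact_max_default)
  if (length(ex) > 0) {
    ex_pos <- stats_tbl$position[ex]
    sub <- dt[dt$position %in% ex_pos, ]
    split_sig <- split(sub, by = "position", keep.by = TRUE)
    u_p[ex] <- vapply(as.character(ex_pos), function(p) {
      s <- split_sig[[p]]
      u_exact_pvalue(s$signal[s$grp == 1L], s$signal[s$grp == 2L])
    }, numeric(1))
  }

  t_p <- welch_pvalue(stats_tbl$m1, stats_tbl$m2, stats_tbl$v1, stats_tbl$v2,
                      stats_tbl$n1, stats_tbl$n2)

  out <- tibble(
    position = as.integer(stats_tbl$position),
    cov_native = as.integer(stats_tbl$n1),
    cov_wga = as.integer(stats_tbl$n2),
    mean_diff = stats_tbl$m1 - stats_tbl$m2,
    u_pvalue = u_p,
    t_pvalue = t_p
  )
  out <- arrange(out, .data$position)
  structure(out, class = c("difference_table", class(tibble())))
}

#' Write / read a difference table as TSV
#'
#' Header `position cov_native cov_wga mean_diff u_pvalue t_pvalue`.
#'
#' @param diff A difference table.
#' @param path File path.
#' @return `write_difference_table_tsv()` returns `path` invisibly.
#' @export
write_difference_table_tsv <- function(diff, path) {
  utils::write.table(as_tibble(diff), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_difference_table_tsv
#' @export
read_difference_table_tsv <- function(path) {
  tbl <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  tbl$position <- as.integer(tbl$position)
  structure(tbl, class = c("difference_table", class(tibble())))
}

#' Summarize an in-silico titration
#'
#' For each motif and each native-read fraction, summarizes the distribution of
#' site p-values (minimum U p-value over the focal base ±1): quartiles and site
#' count. Shows whether test sensitivity tracks the fraction of methylated
#' molecules.
#'
#' @param diff_tables Named list: names are native fractions (as numbers, e.g.
#'   `"0"`, `"0.25"`, ... ), values are difference tables. The grid must
#'   include 0 and 1.
#' @param motif_sites Named list: motif name → integer vector of focal
#'   positions (or a [scan_motifs()] tibble).
#' @return A tibble of class `"titration_summary"` with columns `motif`,
#'   `fraction_native`, `n_sites`, `p_q25`, `p_median`, `p_q75`.
#' @export
summarize_titration <- function(diff_tables, motif_sites) {
  fr <- suppressWarnings(as.numeric(names(diff_tables)))
  if (any(is.na(fr))) abort("names of `diff_tables` must be native fractions")
  if (!any(fr == 0) || !any(fr == 1)) {
    abort("the titration fraction grid must include 0 and 1")
  }
  out <- purrr::map_dfr(seq_along(diff_tables), function(i) {
    diff <- diff_tables[[i]]
    purrr::map_dfr(names(motif_sites), function(mname) {
      focal <- motif_sites[[mname]]
      if (is.data.frame(focal)) focal <- focal$focal_position
      p <- site_pvalues(diff, focal)
      p <- p[!is.na(p)]
      q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
      tibble(motif = mname, fraction_native = fr[i], n_sites = length(p),
             p_q25 = q[1], p_median = q[2], p_q75 = q[3])
    })
  })
  out <- arrange(out, .data$motif, .data$fraction_native)
  structure(out, class = c("titration_summary", class(tibble())))
}
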