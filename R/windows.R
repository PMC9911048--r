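#' Windowed methylation-fraction profile
#'
#' Tiles the genome into fixed-size windows, counts motif sites (the number of
#' potential modifications) and methylated calls per window, and reports the
#' methylated fraction. Windows containing no motif site are excluded from the
#' profile (kept in `attr(, "excluded_windows")`). Optional coverage tracks on
#' the same window grid attach mean native/WGA coverage per window for use as
#' partial-correlation covariates.
#'
#' @param calls A [classify_sites()] tibble (one condition).
#' @param sites The full [scan_motifs()] site list for the same genome (the
#'   denominator; sites that could not be scored still count as potential
#'   modifications).
#' @param genome_length Genome length in bases.
#' @param window Window width in bases (default 10,000).
#' @param coverage_tracks Optional `list(native = , wga = )` of
#'   [coverage_track()] tibbles on the same window grid.
#' @return A tibble of class `"window_profile"`: `condition`, `motif`,
#'   `window_index`, `window_start`, `n_sites`, `n_methylated`, `fraction`,
#'   `mean_cov_native`, `mean_cov_wga`.
#' @export
window_fractions <- function(calls, sites, genome_length, window = 10000L,
                             coverage_tracks = NULL) {
  if (window <= 0) abort("`window` must be positive")
  win <- genome_windows(genome_length, window)
  nw <- nrow(win)
  condition <- if (nrow(calls) > 0) calls$condition[1] else "condition_1"

  prof <- purrr::map_dfr(unique(sites$motif), function(mname) {
    s <- sites[sites$motif == mname, , drop = FALSE]
    c_m <- calls[calls$motif == mname & calls$methylated, , drop = FALSE]
    n_sites <- tabulate(window_index(s$focal_position, window) + 1L, nw)
    n_meth <- tabulate(window_index(c_m$focal_position, window) + 1L, nw)
    tibble(condition = condition, motif = mname,
           window_index = win$window_index, window_start = win$window_start,
           n_sites = n_sites, n_methylated = n_meth,
           fraction = ifelse(n_sites > 0, n_meth / n_sites, NA_real_))
  })

  if (!is.null(coverage_tracks)) {
    lk <- function(tr) tr$coverage[match(prof$window_index, tr$window_index)]
    prof$mean_cov_native <- lk(coverage_tracks$native)
    prof$mean_cov_wga <- lk(coverage_tracks$wga)
  } else {
    prof$mean_cov_native <- NA_real_
    prof$mean_cov_wga <- NA_real_
  }

  excluded <- prof[prof$n_sites == 0, c("motif", "window_index", "window_start")]
  prof <- prof[prof$n_sites > 0, , drop = FALSE]
  structure(prof, window_size = as.integer(window),
            genome_length = as.integer(genome_length),
            excluded_windows = excluded,
            class = c("window_profile", class(tibble())))
}

#' Normalize a window profile by its genome-wide mean
#'
#' Divides each window's methylated fraction by the unweighted mean fraction
#' over included windows (per condition × motif), so the normalized profile
#' has mean 1 and is comparable across conditions with different overall
#' methylation levels.
#'
#' @param profile A [window_fractions()] tibble.
#' @return The profile with `fraction` rescaled (original kept as
#'   `fraction_raw`).
#' @export
normalize_profile <- function(profile) {
  if (nrow(profile) == 0) abort("empty profile")
  out <- profile %>%
    group_by(.data$condition, .data$motif) %>%
    mutate(fraction_raw = .data$fraction,
           fraction = .data$fraction / mean(.data$fraction)) %>%
    ungroup()
  if (any(!is.finite(out$fraction))) {
    abort("normalize_profile(): a condition x motif group has all-zero fractions")
  }
  attributes(out)[c("window_size", "genome_length", "excluded_windows")] <-
    attributes(profile)[c("window_size", "genome_length", "excluded_windows")]
  structure(out, class = unique(c("window_profile", class(out))))
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length ≥ 3 with nonzero variance.
#' @return A list with `r`, `pvalue`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x))
}

#' Partial Pearson correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and returns the Pearson correlation of the residuals, with a
#' two-sided t p-value on `n - 2 - k` degrees of freedom (`k` covariates).
#' Used to correlate methylation fractions between conditions while
#' controlling for sequencing coverage, which affects the chance a site is
#' detected as modified.
#'
#' @param x,y Numeric vectors.
#' @param covariates List (possibly named) of numeric covariate vectors, a
#'   matrix, or empty for a plain Pearson correlation.
#' @return A list with `r`, `pvalue`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = list()) {
  if (is.matrix(covariates) || is.data.frame(covariates)) {
    covariates <- as.list(as.data.frame(covariates))
  }
  if (length(covariates) == 0) return(c(pearson(x, y), list(df = length(x) - 2)))
  n <- length(x)
  if (any(vapply(covariates, length, integer(1)) != n) || length(y) != n) {
    abort("all vectors must have equal length")
  }
  k <- length(covariates)
  if (n <= k + 2) abort("need more observations than covariates + 2")
  Z <- cbind(`(intercept)` = 1, do.call(cbind, covariates))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    abort(sprintf("collinear covariates: %s", paste(dropped, collapse = ", ")))
  }
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    abort("undefined correlation: zero residual variance")
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, pvalue = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Pairwise condition correlation matrix
#'
#' For every unordered pair of conditions and every motif, correlates the
#' per-window methylated fractions over windows included in both profiles,
#' optionally as a partial correlation controlling for per-window sequencing
#' coverage (default: each condition's native coverage plus the shared WGA
#' coverage, when coverage is attached to the profiles).
#'
#' @param profiles Named list of [window_fractions()] profiles, one per
#'   condition, on the same genome and window grid.
#' @param covariates `"coverage"` (default; falls back to `"none"` when the
#'   profiles carry no coverage) or `"none"`.
#' @param p_adjust If `TRUE`, adds Benjamini-Hochberg adjusted p-values per
#'   motif across the pair matrix.
#' @return A tibble of class `"condition_matrix"`: `motif`, `condition_a`,
#'   `condition_b`, `r`, `pvalue`, `n_windows`, `covariates`. Pairs with
#'   fewer than 3 shared windows yield `NA` with a warning.
#' @export
pairwise_condition_matrix <- function(profiles, covariates = c("coverage", "none"),
                                      p_adjust = FALSE) {
  covariates <- match.arg(covariates)
  if (length(profiles) < 2) abort("need at least two condition profiles")
  if (is.null(names(profiles))) {
    names(profiles) <- purrr::map_chr(profiles, ~ .x$condition[1])
  }
  conds <- names(profiles)
  motifs <- unique(unlist(purrr::map(profiles, ~ unique(.x$motif))))
  pairs <- combn(conds, 2)

  out <- purrr::map_dfr(motifs, function(mname) {
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      pa <- profiles[[a]][profiles[[a]]$motif == mname, , drop = FALSE]
      pb <- profiles[[b]][profiles[[b]]$motif == mname, , drop = FALSE]
      shared <- intersect(pa$window_index, pb$window_index)
      if (length(shared) < 3) {
        warn(sprintf("pair (%s, %s) motif %s: fewer than 3 shared windows", a, b, mname))
        return(tibble(motif = mname, condition_a = a, condition_b = b,
                      r = NA_real_, pvalue = NA_real_,
                      n_windows = length(shared), covariates = "none"))
      }
      ia <- match(shared, pa$window_index)
      ib <- match(shared, pb$window_index)
      use_cov <- covariates == "coverage" &&
        !all(is.na(pa$mean_cov_native[ia])) && !all(is.na(pb$mean_cov_native[ib]))
      if (use_cov) {
        covs <- list(
          cov_native_a = pa$mean_cov_native[ia],
          cov_native_b = pb$mean_cov_native[ib],
          cov_wga = (pa$mean_cov_wga[ia] + pb$mean_cov_wga[ib]) / 2
        )
        res <- partial_correlation(pa$fraction[ia], pb$fraction[ib], covs)
        cov_label <- paste(names(covs), collapse = "+")
      } else {
        res <- pearson(pa$fraction[ia], pb$fraction[ib])
        cov_label <- "none"
      }
      tibble(motif = mname, condition_a = a, condition_b = b,
             r = res$r, pvalue = res$pvalue, n_windows = length(shared),
             covariates = cov_label)
    })
  })
  if (p_adjust) {
    out <- out %>%
      group_by(.data$motif) %>%
      mutate(pvalue_bh = p.adjust(.data$pvalue, "BH")) %>%
      ungroup()
  }
  structure(out, class = c("condition_matrix", class(tibble())))
}

#' Long-range correlation scan of the methylation profile
#'
#' Autocorrelation-style scan: for each window size `w` the genome is tiled at
#' step `w` and per-window methylated fractions computed; for each separation
#' `d` the fractions of window pairs whose gap is `d` bases (index lag
#' `1 + round(d / w)`; `d = 0` means adjacent windows, and `d = -w` is the
#' degenerate self-correlation sanity lag) are correlated. Zero-site windows
#' are dropped pairwise; cells with fewer than 3 pairs are recorded as
#' missing.
#'
#' @param calls A [classify_sites()] tibble (one condition and motif, or
#'   filtered beforehand).
#' @param sites The matching [scan_motifs()] site list.
#' @param genome_length Genome length in bases.
#' @param window_sizes Window widths in bases (e.g. 250 to 500,000).
#' @param separations Gaps in bases between the paired windows (0 to 1e6).
#' @return A tibble of class `"long_range_grid"`: `window_size`, `separation`,
#'   `r`, `n_pairs`.
#' @export
long_range_scan <- function(calls, sites, genome_length,
                            window_sizes = c(250, 1000, 10000, 100000, 500000),
                            separations = c(0, 10000, 100000, 1000000)) {
  if (any(window_sizes <= 0)) abort("window sizes must be positive")
  if (any(window_sizes > genome_length / 4)) {
    abort("window sizes must be at most a quarter of the genome")
  }
  out <- purrr::map_dfr(window_sizes, function(w) {
    nw <- nrow(genome_windows(genome_length, w))
    n_sites <- tabulate(window_index(sites$focal_position, w) + 1L, nw)
    meth <- calls[calls$methylated, , drop = FALSE]
    n_meth <- tabulate(window_index(meth$focal_position, w) + 1L, nw)
    frac <- ifelse(n_sites > 0, n_meth / n_sites, NA_real_)
    purrr::map_dfr(separations, function(d) {
      lag <- if (d == -w) 0L else 1L + as.integer(round(d / w))
      if (lag < 0 || lag >= nw) {
        return(tibble(window_size = w, separation = d, r = NA_real_,
                      n_pairs = 0L))
      }
      i <- seq_len(nw - lag)
      xa <- frac[i]; xb <- frac[i + lag]
      ok <- !is.na(xa) & !is.na(xb)
      if (sum(ok) < 3 || stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0) {
        return(tibble(window_size = w, separation = d, r = NA_real_,
                      n_pairs = sum(ok)))
      }
      tibble(window_size = w, separation = d, r = cor(xa[ok], xb[ok]),
             n_pairs = sum(ok))
    })
  })
  structure(out, class = c("long_range_grid", class(out)))
}

#' Write a window profile as TSV, or its fraction track as BEDGRAPH
#'
#' @param profile A [window_fractions()] tibble.
#' @param path Output path.
#' @param contig_id Contig name (BEDGRAPH only).
#' @return `path`, invisibly.
#' @export
write_window_profile_tsv <- function(profile, path) {
  utils::write.table(as_tibble(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_profile_tsv
#' @export
write_window_profile_bedgraph <- function(profile, path, contig_id = "contig_1") {
  w <- attr(profile, "window_size")
  bed <- data.frame(chrom = contig_id, start = profile$window_start,
                    end = profile$window_start + w, value = profile$fraction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write any result tibble (correlation matrix, long-range grid) as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
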