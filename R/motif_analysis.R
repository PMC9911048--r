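#' Site p-value: minimum over the focal base and its neighbours
#'
#' The methylation perturbs the pore signal over several bases, so the U-test
#' p-value is not necessarily lowest exactly at the modified base. A motif
#' site's p-value is therefore the minimum `u_pvalue` over the focal position
#' and either neighbouring position, taken over whichever of the three
#' positions are present in the difference table. Sites with none of the three
#' present get `NA` and are excluded downstream.
#'
#' @param diff A [difference_table()].
#' @param focal_positions Integer vector of 0-based focal coordinates.
#' @return Numeric vector of site p-values (with `NA` sentinels), one per
#'   input position.
#' @export
site_pvalues <- function(diff, focal_positions) {
  focal_positions <- as.integer(focal_positions)
  p <- diff$u_pvalue
  pos <- diff$position
  m <- cbind(p[match(focal_positions - 1L, pos)],
             p[match(focal_positions, pos)],
             p[match(focal_positions + 1L, pos)])
  out <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' @rdname site_pvalues
#' @param focal_position A single focal coordinate.
#' @export
site_pvalue <- function(diff, focal_position) {
  site_pvalues(diff, focal_position)
}

#' Empirical null distribution from random genomic positions
#'
#' Draws `n_sites` positions uniformly without replacement from the first
#' `region_end` bases of the genome (presumed overwhelmingly unmethylated),
#' scores each with the same minimum-over-±1 rule as real motif sites, and
#' sets the classification threshold at a low percentile (default the 10th) of
#' these null p-values. Restricting the null to the genome start (default
#' 1 Mbp) only limits compute; random positions are exchangeable along the
#' genome.
#'
#' @param diff A [difference_table()].
#' @param n_sites Number of random null positions (> 0).
#' @param region_end Null region is `[0, region_end)` (default 1e6); clipped
#'   to the genome when `genome_length` is given.
#' @param threshold_percentile Percentile of the null used as the calling
#'   threshold (default 10, i.e. a designed 10% false-positive rate).
#' @param genome_length Optional genome length for validation.
#' @param exclude Optional positions (e.g. motif flanks) removed from the
#'   sampling frame, for a purified null.
#' @param positions Optional pre-drawn null positions (overrides sampling);
#'   used when the caller must know the null positions before computing the
#'   difference table, e.g. in targeted-signal runs.
#' @param seed Integer seed.
#' @return An object of class `"null_distribution"`: list with `pvalues`
#'   (non-missing null site p-values), `n_sites`, `region`,
#'   `threshold_percentile`, `threshold`.
#' @export
build_null <- function(diff, n_sites = 1000L, region_end = 1e6,
                       threshold_percentile = 10, genome_length = NULL,
                       exclude = NULL, positions = NULL, seed = NULL) {
  if (!is.null(genome_length) && region_end > genome_length) {
    region_end <- genome_length
  }
  if (is.null(positions)) {
    if (n_sites <= 0) abort("`n_sites` must be positive")
    frame <- 0:(as.integer(region_end) - 1L)
    if (!is.null(exclude)) frame <- setdiff(frame, as.integer(exclude))
    if (n_sites > length(frame)) {
      abort("`n_sites` exceeds the number of candidate null positions")
    }
    positions <- with_seed_if(seed, sort(sample(frame, n_sites)))
  } else {
    positions <- sort(as.integer(positions))
    n_sites <- length(positions)
  }
  pvals <- site_pvalues(diff, positions)
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) {
    abort("no null position overlaps the difference table")
  }
  threshold <- quantile_nearest_lower(pvals, threshold_percentile)
  # nearest-rank-lower + strict inequality guarantee at most the stated
  # fraction of the null's own p-values below the threshold
  stopifnot(mean(pvals < threshold) <= threshold_percentile / 100)
  structure(
    list(pvalues = pvals, n_sites = as.integer(n_sites),
         region = c(0L, as.integer(region_end)),
         threshold_percentile = threshold_percentile, threshold = threshold),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %d sites in [%d, %d), threshold %.4g at the %gth percentile>\n",
    length(x$pvalues), x$region[1], x$region[2], x$threshold,
    x$threshold_percentile))
  invisible(x)
}

#' Binary methylation calls for motif sites
#'
#' A site is called methylated exactly when its p-value is strictly lower than
#' the null threshold; all other scorable sites are called unmethylated. Sites
#' with no scorable position (no coverage at focal ±1) are dropped.
#'
#' @param sites A [scan_motifs()] tibble.
#' @param diff A [difference_table()] from the same run.
#' @param null A [build_null()] result from the same difference table.
#' @param condition Condition label attached to the calls.
#' @return A tibble of class `"site_calls"` with columns `condition`, `motif`,
#'   `start`, `strand`, `focal_position`, `site_pvalue`, `methylated`; the
#'   threshold used is in `attr(, "threshold")`.
#' @export
classify_sites <- function(sites, diff, null, condition = "condition_1") {
  if (!inherits(null, "null_distribution")) {
    abort("`null` must be a null_distribution")
  }
  if (nrow(sites) == 0) {
    out <- tibble(condition = character(), motif = character(),
                  start = integer(), strand = character(),
                  focal_position = integer(), site_pvalue = double(),
                  methylated = logical())
    return(structure(out, threshold = null$threshold,
                     class = c("site_calls", class(tibble()))))
  }
  p <- site_pvalues(diff, sites$focal_position)
  out <- tibble(
    condition = condition,
    motif = sites$motif,
    start = sites$start,
    strand = sites$strand,
    focal_position = sites$focal_position,
    site_pvalue = p,
    methylated = p < null$threshold
  )
  out <- filter(out, !is.na(.data$site_pvalue))
  structure(out, threshold = null$threshold,
            class = c("site_calls", class(tibble())))
}

#' Export low-p-value flanking regions for external motif discovery
#'
#' Uniformly subsamples positions (with their p-values) from the difference
#' table, ranks them by U p-value ascending (ties broken by a seeded shuffle),
#' keeps the `top_n` lowest, and emits the flanking sequence of each as a
#' FASTA-ready `DNAStringSet` — input for a motif finder such as MEME, which
#' is outside this package's scope.
#'
#' @param diff A [difference_table()].
#' @param genome The genome the table was computed on.
#' @param subsample_bp Number of positions to subsample (default 100,000).
#' @param top_n Number of lowest-p positions to keep (default 5,000).
#' @param flank Bases kept on either side of each position (default 10).
#' @param seed Integer seed.
#' @return A `DNAStringSet`, one record per selected position, named
#'   `contig:start-end` (0-based half-open); attributes `n_sampled` and
#'   `sampled_fraction` (of the genome) record the subsampling.
#' @export
extract_candidate_regions <- function(diff, genome, subsample_bp = 100000L,
                                      top_n = 5000L, flank = 10L,
                                      seed = NULL) {
  seq <- as_genome_seq(genome)
  glen <- length(seq)
  if (flank >= glen) abort("`flank` must be smaller than the genome")
  if (subsample_bp > glen) abort("`subsample_bp` exceeds the genome length")
  if (top_n > subsample_bp) abort("`top_n` must not exceed `subsample_bp`")
  if (subsample_bp > nrow(diff)) {
    abort("`subsample_bp` exceeds the number of scored positions")
  }
  with_seed_if(seed, {
    pick <- sample.int(nrow(diff), subsample_bp)
    sub <- diff[pick, , drop = FALSE]
    ord <- order(sub$u_pvalue, runif(nrow(sub)))  # seeded tie shuffle
    sel <- sub[ord[seq_len(top_n)], , drop = FALSE]
    lo <- pmax(0L, sel$position - as.integer(flank))
    hi <- pmin(glen, sel$position + as.integer(flank) + 1L)
    out <- Biostrings::DNAStringSet(seq, start = lo + 1L, end = hi)
    names(out) <- sprintf("%s:%d-%d", "contig_1", lo, hi)
    attr(out, "n_sampled") <- as.integer(subsample_bp)
    attr(out, "sampled_fraction") <- subsample_bp / glen
    out
  })
}

#' Write site calls as BED6+2 and TSV
#'
#' BED columns: chrom, start, end (focal base, half-open), name (motif),
#' score (`-log10` site p-value, capped at 1000), strand, then site p-value
#' and the methylated flag.
#'
#' @param calls A [classify_sites()] tibble.
#' @param path Output path.
#' @param contig_id Contig name.
#' @return `path`, invisibly.
#' @export
write_site_calls_bed <- function(calls, path, contig_id = "contig_1") {
  score <- pmin(1000, round(-log10(pmax(calls$site_pvalue, 1e-300)), 3))
  bed <- data.frame(chrom = contig_id, start = calls$focal_position,
                    end = calls$focal_position + 1L, name = calls$motif,
                    score = score, strand = calls$strand,
                    site_pvalue = calls$site_pvalue,
                    methylated = calls$methylated)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_site_calls_bed
#' @export
write_site_calls_tsv <- function(calls, path) {
  utils::write.table(as_tibble(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a null distribution as TSV (threshold in a header comment)
#'
#' @param null A [build_null()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_tsv <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold\t%.17g\t(percentile %g, n_sites %d)",
                     null$threshold, null$threshold_percentile, null$n_sites),
             con)
  writeLines("pvalue", con)
  writeLines(sprintf("%.17g", null$pvalues), con)
  invisible(path)
}
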