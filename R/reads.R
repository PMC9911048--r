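new_read_set <- function(reads, marks, genome_length) {
  structure(
    reads,
    marks = marks,
    genome_length = as.integer(genome_length),
    class = c("read_set", class(tibble()))
  )
}

#' Per-molecule methylation marks of a read set
#'
#' @param reads A read set from [simulate_reads()] or [mix_reads()].
#' @return A tibble with columns `read_id`, `focal_position` listing every
#'   (molecule, site) pair that carries a methyl mark. WGA reads never appear.
#' @export
read_marks <- function(reads) {
  m <- attr(reads, "marks")
  if (is.null(m)) tibble(read_id = character(), focal_position = integer()) else m
}

# subset a read set by row index, carrying marks and attributes along
subset_read_set <- function(reads, idx) {
  tbl <- as_tibble(reads)[idx, , drop = FALSE]
  marks <- read_marks(reads)
  new_read_set(tbl, marks[marks$read_id %in% tbl$read_id, , drop = FALSE],
               attr(reads, "genome_length"))
}

#' Simulate nanopore reads over a genome
#'
#' Read starts are uniform over the genome; lengths follow a geometric-like
#' distribution (`1 + Geometric`) with the stated mean, truncated at the genome
#' end (no circular wrap). The number of reads is
#' `round(coverage * genome_length / read_length_mean)`. When a methylation
#' landscape is supplied, each read is a molecule: at every overlapped motif
#' site a methyl mark is drawn `Bernoulli(theta)` independently across sites.
#' Without a landscape the read set is an unmethylated WGA control.
#'
#' @param genome A genome (see [generate_genome()]).
#' @param landscape A [build_landscape()] result, or `NULL` for a WGA sample.
#' @param condition Condition label to pull `theta` from the landscape
#'   (defaults to its first condition).
#' @param coverage Target fold coverage (> 0).
#' @param read_length_mean Mean read length in bases (default 5,000).
#' @param sample_label Sample name stored per read (defaults to `"native"`
#'   with a landscape, `"wga"` without).
#' @param id_prefix Prefix for read identifiers (defaults to the sample label).
#' @param seed Integer seed.
#' @return A tibble of class `"read_set"` with columns `read_id`, `sample`,
#'   `start`, `length` (0-based, half-open) and the methyl marks in
#'   `attr(, "marks")` (see [read_marks()]).
#' @export
simulate_reads <- function(genome, landscape = NULL, condition = NULL,
                           coverage = 50, read_length_mean = 5000,
                           sample_label = NULL, id_prefix = NULL, seed = NULL) {
  glen <- genome_length(genome)
  if (!is.numeric(coverage) || coverage <= 0) abort("`coverage` must be > 0")
  if (read_length_mean > glen) {
    abort("`read_length_mean` exceeds the genome length")
  }
  if (is.null(sample_label)) {
    sample_label <- if (is.null(landscape)) "wga" else "native"
  }
  if (is.null(id_prefix)) id_prefix <- sample_label
  n_reads <- as.integer(round(coverage * glen / read_length_mean))

  with_seed_if(seed, {
    start <- as.integer(floor(runif(n_reads, 0, glen)))
    len <- 1L + rgeom(n_reads, 1 / read_length_mean)
    len <- pmin(len, glen - start)
    reads <- tibble(
      read_id = paste0(id_prefix, "_", seq_len(n_reads)),
      sample = sample_label,
      start = start,
      length = as.integer(len)
    )
    marks <- tibble(read_id = character(), focal_position = integer())
    if (!is.null(landscape)) {
      if (is.null(condition)) condition <- landscape$condition[1]
      theta <- landscape_theta(landscape, condition)
      site_pos <- as.integer(names(theta))
      # overlapped site range per read on the sorted site vector
      lo <- findInterval(reads$start - 0.5, site_pos) + 1L
      hi <- findInterval(reads$start + reads$length - 0.5, site_pos)
      n_over <- pmax(0L, hi - lo + 1L)
      keep <- n_over > 0L
      if (any(keep)) {
        ridx <- rep(which(keep), n_over[keep])
        sidx <- sequence(n_over[keep], from = lo[keep])
        hit <- rbinom(length(sidx), 1L, theta[sidx]) == 1L
        marks <- tibble(
          read_id = reads$read_id[ridx[hit]],
          focal_position = site_pos[sidx[hit]]
        )
      }
    }
    new_read_set(reads, marks, glen)
  })
}

#' Mix native and WGA reads in silico
#'
#' Draws reads without replacement from a native and a WGA pool so that the
#' output approximates a target fold coverage with the stated native share by
#' read count — the in-silico titration used to show that site p-values track
#' the fraction of methylated molecules.
#'
#' @param native,wga Read sets over the same genome.
#' @param fraction_native Share of output reads drawn from the native pool,
#'   in `[0, 1]`.
#' @param target_coverage Fold coverage the mixture should approximate.
#' @param seed Integer seed.
#' @return A `"read_set"` tibble; reads keep their original `sample` labels
#'   and methyl marks.
#' @export
mix_reads <- function(native, wga, fraction_native, target_coverage,
                      seed = NULL) {
  check_fraction(fraction_native, "fraction_native")
  glen <- attr(native, "genome_length")
  if (is.null(glen)) abort("`native` must be a read_set with a genome_length attribute")
  ml_nat <- mean(native$length)
  ml_wga <- mean(wga$length)
  ml_mix <- fraction_native * ml_nat + (1 - fraction_native) * ml_wga
  n_total <- as.integer(round(target_coverage * glen / ml_mix))
  n_native <- as.integer(round(fraction_native * n_total))
  n_wga <- n_total - n_native
  if (n_native > nrow(native)) {
    abort(sprintf("native pool has %d reads but %d are required",
                  nrow(native), n_native))
  }
  if (n_wga > nrow(wga)) {
    abort(sprintf("wga pool has %d reads but %d are required",
                  nrow(wga), n_wga))
  }
  with_seed_if(seed, {
    pick_nat <- sample.int(nrow(native), n_native)
    pick_wga <- sample.int(nrow(wga), n_wga)
    out <- bind_rows(as_tibble(native)[pick_nat, , drop = FALSE],
                     as_tibble(wga)[pick_wga, , drop = FALSE])
    marks <- read_marks(native)
    new_read_set(out, marks[marks$read_id %in% out$read_id, , drop = FALSE],
                 glen)
  })
}

#' Write / read a read set as TSV
#'
#' Columns `read_id`, `sample`, `start`, `length`; methyl marks go to a
#' sidecar BED3+1 (`<path>.marks.bed`: contig, focal, focal+1, read_id) when
#' present.
#'
#' @param reads A read set.
#' @param path Output TSV path.
#' @param genome_length Genome length, required by `read_read_set_tsv()`.
#' @param contig_id Contig name used in the marks BED.
#' @return `write_read_set_tsv()` returns `path` invisibly.
#' @export
write_read_set_tsv <- function(reads, path, contig_id = "contig_1") {
  utils::write.table(as_tibble(reads)[c("read_id", "sample", "start", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  marks <- read_marks(reads)
  if (nrow(marks) > 0) {
    bed <- data.frame(chrom = contig_id, start = marks$focal_position,
                      end = marks$focal_position + 1L, name = marks$read_id)
    utils::write.table(bed, paste0(path, ".marks.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_read_set_tsv
#' @export
read_read_set_tsv <- function(path, genome_length) {
  tbl <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     colClasses = c("character", "character",
                                                    "integer", "integer")))
  marks_path <- paste0(path, ".marks.bed")
  marks <- if (file.exists(marks_path)) {
    b <- utils::read.table(marks_path, sep = "\t")
    tibble(read_id = as.character(b[[4]]), focal_position = as.integer(b[[2]]))
  } else {
    tibble(read_id = character(), focal_position = integer())
  }
  new_read_set(tbl, marks, genome_length)
}
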