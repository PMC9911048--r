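#' Nanopore signal model for the simulator
#'
#' Signals follow a fixed-baseline Gaussian shift model: each genome position
#' has a deterministic, seeded baseline current shared exactly by native and
#' WGA samples, and a methylated molecule shifts the signal by `delta` at every
#' position within `halfwidth_k` bases of the modified base (the pore reads
#' several bases at once, so the perturbation is local but not single-base).
#' The 5mC shift is larger than the 6mA shift by default, which reproduces the
#' observation that Dcm (CCWGG) methylation is detected much more sensitively
#' than Dam (GATC) methylation at equal coverage.
#'
#' @param sigma Per-event Gaussian noise SD in signal units (> 0), default 1.
#' @param delta_6mA,delta_5mC Signal shift magnitudes for the two modification
#'   types (defaults 0.5 and 1.2).
#' @param halfwidth_k Bases on either side of the focal base affected by the
#'   shift (≥ 1, default 2).
#' @param baseline_mean,baseline_sd Mean and positional SD of the baseline
#'   current (defaults 100 and 10 arbitrary units).
#' @param baseline_seed Seed of the positional baseline; fixed across samples
#'   so that native-vs-WGA differences come only from methylation and noise.
#' @return A list of class `"signal_model"`.
#' @export
signal_model <- function(sigma = 1, delta_6mA = 0.5, delta_5mC = 1.2,
                         halfwidth_k = 2L, baseline_mean = 100,
                         baseline_sd = 10, baseline_seed = 20260901L) {
  if (sigma <= 0) abort("`sigma` must be positive")
  if (halfwidth_k < 1) abort("`halfwidth_k` must be at least 1")
  structure(
    list(sigma = sigma, delta_6mA = delta_6mA, delta_5mC = delta_5mC,
         halfwidth_k = as.integer(halfwidth_k), baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, baseline_seed = as.integer(baseline_seed)),
    class = "signal_model"
  )
}

#' Baseline current at genome positions
#'
#' Deterministic seeded baseline: the same model always maps a position to the
#' same current, so native and WGA samples share the baseline exactly.
#'
#' @param model A [signal_model()].
#' @param positions 0-based positions.
#' @param genome_length Genome length in bases.
#' @return Numeric vector of baseline currents.
#' @export
baseline_mu <- function(model, positions, genome_length) {
  base <- withr::with_seed(
    model$baseline_seed,
    rnorm(genome_length, model$baseline_mean, model$baseline_sd)
  )
  base[positions + 1L]
}

# delta by modification type
model_delta <- function(model, modification) {
  switch(modification, "6mA" = model$delta_6mA, "5mC" = model$delta_5mC,
         "4mC" = model$delta_5mC, abort("unknown modification type"))
}

#' Simulate a per-read, per-position signal event table
#'
#' Emits one signal observation per (read, covered position):
#' `baseline + delta * methylated-within-k + Normal(0, sigma)`, where the shift
#' applies at positions within `halfwidth_k` bases of a focal site at which the
#' molecule carries a methyl mark. WGA reads and unmethylated molecules draw
#' from the baseline alone.
#'
#' For large genomes the full table (coverage × genome length rows) is rarely
#' needed: `positions` restricts emission to a stated position set (e.g. motif
#' focal bases ±1 plus null positions), which leaves the per-position signal
#' distribution unchanged because events are independent across positions given
#' the reads.
#'
#' @param reads A read set.
#' @param model A [signal_model()].
#' @param modification Modification type whose `delta` applies to marked sites
#'   (`"6mA"`, `"5mC"`, `"4mC"`); ignored when `site_modifications` is given.
#' @param site_modifications Optional named character vector mapping focal
#'   position → modification type, for genomes carrying several motif types at
#'   once.
#' @param positions Optional integer vector of 0-based positions: only events
#'   at these positions are emitted.
#' @param genome_length Genome length; defaults to the read set's attribute.
#' @param seed Integer seed.
#' @return A tibble of class `"event_table"` with columns `position`,
#'   `read_id`, `sample`, `signal`.
#' @export
simulate_signals <- function(reads, model = signal_model(),
                             modification = "6mA", site_modifications = NULL,
                             positions = NULL, genome_length = NULL,
                             seed = NULL) {
  glen <- genome_length %||% attr(reads, "genome_length")
  if (is.null(glen)) abort("genome_length is required")
  tbl <- as_tibble(reads)
  if (any(tbl$start + tbl$length > glen)) abort("reads extend past the genome")

  if (is.null(positions)) {
    pos_idx <- NULL
  } else {
    pos_idx <- sort(unique(as.integer(positions)))
    if (any(pos_idx < 0 | pos_idx >= glen)) abort("`positions` outside genome")
  }

  # expand (read, position) pairs
  if (is.null(pos_idx)) {
    n_per <- tbl$length
    ridx <- rep(seq_len(nrow(tbl)), n_per)
    pos <- sequence(n_per, from = tbl$start)
  } else {
    lo <- findInterval(tbl$start - 0.5, pos_idx) + 1L
    hi <- findInterval(tbl$start + tbl$length - 0.5, pos_idx)
    n_per <- pmax(0L, hi - lo + 1L)
    keep <- n_per > 0L
    ridx <- rep(which(keep), n_per[keep])
    pos <- pos_idx[sequence(n_per[keep], from = lo[keep])]
  }
  if (length(ridx) == 0) {
    return(structure(tibble(position = integer(), read_id = character(),
                            sample = character(), signal = double()),
                     class = c("event_table", class(tibble()))))
  }

  mu <- baseline_mu(model, pos, glen)

  # shift: positions within k of a marked focal site of the same molecule
  marks <- read_marks(reads)
  shift <- numeric(length(pos))
  if (nrow(marks) > 0) {
    k <- model$halfwidth_k
    marks_dt <- data.table::data.table(
      read_id = marks$read_id,
      lo = marks$focal_position - k,
      hi = marks$focal_position + k,
      delta = if (is.null(site_modifications)) {
        model_delta(model, modification)
      } else {
        vapply(site_modifications[as.character(marks$focal_position)],
               function(m) model_delta(model, m), numeric(1))
      }
    )
    ev_dt <- data.table::data.table(row = seq_along(pos),
                                    read_id = tbl$read_id[ridx],
                                    lo = pos, hi = pos)
    data.table::setkey(marks_dt, read_id, lo, hi)
    ov <- data.table::foverlaps(ev_dt, marks_dt,
                                by.x = c("read_id", "lo", "hi"),
                                type = "within", nomatch = NULL)
    if (nrow(ov) > 0) {
      agg <- ov[, list(delta = sum(delta)), by = "row"]
      shift[agg$row] <- agg$delta
    }
  }

  sig <- with_seed_if(seed, mu + shift + rnorm(length(pos), 0, model$sigma))
  out <- tibble(position = as.integer(pos), read_id = tbl$read_id[ridx],
                sample = tbl$sample[ridx], signal = sig)
  structure(out, class = c("event_table", class(tibble())))
}

#' Subset an event table to the reads of a read set
#'
#' Used by the titration workflow: signals are simulated once per pool, then
#' each in-silico mixture selects its reads' events.
#'
#' @param events An event table.
#' @param reads A read set (or character vector of read ids).
#' @return The filtered event table.
#' @export
events_for_reads <- function(events, reads) {
  ids <- if (is.character(reads)) reads else reads$read_id
  out <- events[events$read_id %in% ids, , drop = FALSE]
  structure(out, class = c("event_table", class(tibble())))
}

#' Write / read an event table as (optionally gzipped) TSV
#'
#' @param events An event table.
#' @param path Output path; a `.gz` suffix gzips the file.
#' @return `write_event_table_tsv()` returns `path` invisibly.
#' @export
write_event_table_tsv <- function(events, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as_tibble(events), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table_tsv
#' @export
read_event_table_tsv <- function(path) {
  tbl <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     colClasses = c("integer", "character",
                                                    "character", "numeric")))
  structure(tbl, class = c("event_table", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
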