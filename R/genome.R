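#' Generate a random genome sequence
#'
#' Draws an i.i.d. base sequence with a given GC fraction (G and C equally
#' likely, likewise A and T). Returned as a single-contig
#' [Biostrings::DNAStringSet] so it plugs directly into FASTA I/O and motif
#' scanning.
#'
#' @param length Genome length in bases (> 0).
#' @param gc_fraction Total probability of G or C at each position, in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param contig_id Name of the contig (default `"contig_1"`).
#' @return A `DNAStringSet` of length 1.
#' @examples
#' g <- generate_genome(10000, gc_fraction = 0.5, seed = 1)
#' Biostrings::width(g)
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                            contig_id = "contig_1") {
  if (!is.numeric(length) || length(length) != 1 || length <= 0) {
    abort("`length` must be a single positive number of bases")
  }
  check_fraction(gc_fraction, "gc_fraction")
  length <- as.integer(length)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- with_seed_if(seed, sample(names(p), length, replace = TRUE, prob = p))
  g <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(g) <- contig_id
  g
}

# Accept a DNAStringSet (first contig), DNAString or plain character and
# return a DNAString
as_genome_seq <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) < 1) abort("empty genome")
    genome[[1]]
  } else if (methods::is(genome, "DNAString")) {
    genome
  } else if (is.character(genome) && length(genome) == 1) {
    Biostrings::DNAString(genome)
  } else {
    abort("`genome` must be a DNAStringSet, DNAString or single character string")
  }
}

genome_length <- function(genome) length(as_genome_seq(genome))

#' Write / read a genome FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param genome A `DNAStringSet`.
#' @param path File path.
#' @return `read_genome_fasta()` returns a `DNAStringSet`;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Define a methyltransferase target motif
#'
#' A motif is an IUPAC pattern plus the 0-based offset of the modified base
#' within it. `rc_closed` (is the pattern its own reverse complement, like GATC
#' or CCWGG?) is derived from the pattern and controls strand handling in
#' [scan_motifs()].
#'
#' @param name Motif label, e.g. `"DAM"` or `"DCM"`.
#' @param iupac IUPAC pattern, e.g. `"GATC"`, `"CCWGG"`.
#' @param focal_offset 0-based index of the modified base within the pattern.
#' @param modification One of `"6mA"`, `"5mC"`, `"4mC"`.
#' @return A list of class `"motif_definition"`.
#' @examples
#' motif_dam() # GATC, 6mA at offset 1
#' motif_dcm() # CCWGG, 5mC at offset 1 (the second C)
#' @export
motif_definition <- function(name, iupac, focal_offset, modification) {
  iupac <- toupper(iupac)
  bad <- setdiff(strsplit(iupac, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC symbol(s) in pattern '%s': %s",
                  iupac, paste(bad, collapse = ", ")))
  }
  modification <- match.arg(modification, c("6mA", "5mC", "4mC"))
  focal_offset <- as.integer(focal_offset)
  if (focal_offset < 0 || focal_offset >= nchar(iupac)) {
    abort("`focal_offset` must lie within the pattern")
  }
  focal_code <- Biostrings::IUPAC_CODE_MAP[[substr(iupac, focal_offset + 1,
                                                   focal_offset + 1)]]
  need <- if (modification == "6mA") "A" else "C"
  if (!grepl(need, focal_code, fixed = TRUE)) {
    abort(sprintf("focal base of a %s motif must be able to be %s",
                  modification, need))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
  structure(
    list(name = name, iupac = iupac, focal_offset = focal_offset,
         modification = modification, rc_closed = identical(rc, iupac)),
    class = "motif_definition"
  )
}

#' @rdname motif_definition
#' @export
motif_dam <- function() motif_definition("DAM", "GATC", 1L, "6mA")

#' @rdname motif_definition
#' @export
motif_dcm <- function() motif_definition("DCM", "CCWGG", 1L, "5mC")

#' @export
print.motif_definition <- function(x, ...) {
  cat(sprintf("<motif %s: %s, %s at offset %d, %s>\n", x$name, x$iupac,
              x$modification, x$focal_offset,
              if (x$rc_closed) "rc-closed" else "strand-specific"))
  invisible(x)
}

#' Locate all motif sites in a genome
#'
#' Scans the forward strand with IUPAC-aware matching. Reverse-complement-closed
#' motifs (GATC, CCWGG) are scanned on the forward strand only, so each
#' double-stranded locus appears exactly once; other motifs are scanned in both
#' orientations with the strand recorded and the focal position mirrored on the
#' minus strand.
#'
#' @param genome A genome (see [generate_genome()]), or a character string.
#' @param motif A [motif_definition()].
#' @return A tibble with columns `motif`, `start` (0-based), `strand`
#'   (`"+"`/`"-"`), `focal_position` (0-based coordinate of the modified base),
#'   sorted by `start`.
#' @examples
#' scan_motifs("GGATCC", motif_dam()) # one site, start 1, focal 2
#' @export
scan_motifs <- function(genome, motif) {
  if (!inherits(motif, "motif_definition")) abort("`motif` must be a motif_definition")
  seq <- as_genome_seq(genome)
  L <- nchar(motif$iupac)

  hit_tbl <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, seq, fixed = "subject")
    start0 <- Biostrings::start(m) - 1L
    if (length(start0) == 0) {
      return(tibble(motif = character(), start = integer(),
                    strand = character(), focal_position = integer()))
    }
    focal <- if (strand == "+") start0 + motif$focal_offset
             else start0 + (L - 1L - motif$focal_offset)
    tibble(motif = motif$name, start = start0, strand = strand,
           focal_position = as.integer(focal))
  }

  out <- hit_tbl(motif$iupac, "+")
  if (!motif$rc_closed) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif$iupac)))
    out <- bind_rows(out, hit_tbl(rc, "-"))
  }
  arrange(out, .data$start, .data$strand)
}
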