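mk_diff <- function(position, u_pvalue) {
  structure(tibble(position = as.integer(position), cov_native = 10L,
                   cov_wga = 10L, mean_diff = 0, u_pvalue = u_pvalue,
                   t_pvalue = u_pvalue),
            class = c("difference_table", class(tibble())))
}

test_that("site p-value is the minimum over focal +/- 1, with sentinels", {
  d <- mk_diff(c(9, 10, 11), c(0.2, 0.5, 0.05))
  expect_equal(site_pvalue(d, 10L), 0.05)
  d2 <- mk_diff(10, 0.3)
  expect_equal(site_pvalue(d2, 10L), 0.3)       # partial window fallback
  expect_true(is.na(site_pvalue(d2, 100L)))     # nothing scorable
  expect_equal(site_pvalues(d, c(10L, 100L)), c(0.05, NA))
})

test_that("build_null draws the requested sites and thresholds by nearest-rank-lower", {
  d <- mk_diff(0:9999, runif(10000))
  nul <- build_null(d, n_sites = 100, region_end = 10000, seed = 1)
  expect_equal(length(nul$pvalues), 100)

  # declared quantile rule on a hand-built null
  d10 <- mk_diff(seq(0, 90, by = 10), seq(0.05, 0.95, by = 0.1))
  nul10 <- build_null(d10, positions = seq(0, 90, by = 10), region_end = 100)
  expect_equal(nul10$threshold, 0.05)

  # quantile convergence on a uniform null (isolated positions so the
  # min-over-±1 rule sees exactly one p-value per site)
  iso <- seq(0L, 299990L, by = 10L)
  big <- build_null(mk_diff(iso, runif(30000)), positions = iso,
                    region_end = 300000)
  expect_lt(abs(big$threshold - 0.10), 0.01)

  expect_error(build_null(d, n_sites = 20000, region_end = 10000, seed = 3),
               "exceeds")

  # threshold tautology: strictly below never exceeds the declared percentile
  for (s in 1:5) {
    n <- build_null(d, n_sites = 37, region_end = 10000, seed = s)
    expect_lte(mean(n$pvalues < n$threshold), 0.10)
  }
})

test_that("classification is a strict threshold rule on site p-values", {
  d <- mk_diff(c(99, 100, 101, 200), c(0.001, 0.5, 0.9, 0.5))
  nul <- build_null(d, positions = c(100L, 200L), region_end = 300,
                    threshold_percentile = 50)
  sites <- tibble(motif = "DAM", start = c(98L, 198L), strand = "+",
                  focal_position = c(100L, 200L))
  calls <- classify_sites(sites, d, nul, "c1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$methylated, calls$site_pvalue < nul$threshold)
  expect_equal(classify_sites(sites[0, ], d, nul)$methylated, logical(0))
})

test_that("null exclusion option removes motif flanks from the frame", {
  d <- mk_diff(0:999, runif(1000))
  banned <- 0:899
  nul <- build_null(d, n_sites = 50, region_end = 1000, exclude = banned,
                    seed = 4)
  # all null p-values must come from positions >= 900 (check via min rule:
  # rebuild with the same seed and frame to recover the positions)
  pos <- withr::with_seed(4L, sort(sample(setdiff(0:999, banned), 50)))
  expect_equal(nul$pvalues, site_pvalues(d, pos)[!is.na(site_pvalues(d, pos))])
})

test_that("candidate-region extraction counts, clips and breaks ties fairly", {
  g <- generate_genome(50000, 0.5, seed = 5)
  d <- mk_diff(0:49999, runif(50000))
  regions <- extract_candidate_regions(d, g, subsample_bp = 10000,
                                       top_n = 500, flank = 10, seed = 6)
  expect_equal(length(regions), 500)
  expect_equal(attr(regions, "n_sampled"), 10000L)
  expect_equal(attr(regions, "sampled_fraction"), 0.2)
  expect_true(all(Biostrings::width(regions) <= 21))

  # all-equal p-values: the selection is a seed-dependent random subset
  dd <- mk_diff(0:9999, rep(0.5, 10000))
  r1 <- extract_candidate_regions(dd, g, 5000, 100, 5, seed = 7)
  r2 <- extract_candidate_regions(dd, g, 5000, 100, 5, seed = 8)
  expect_false(identical(sort(names(r1)), sort(names(r2))))
  expect_error(extract_candidate_regions(d, g, 60000, 10, 5, seed = 9),
               "exceeds")
})

test_that("a planted methylated GATC landscape enriches GATC among top flanks", {
  b <- sim_bundle(genome_len = 1e5, coverage = 50, theta = NULL, seed = 30)
  # methylate GATC fully, leave everything else untouched
  ls <- b$landscape
  ls$theta <- ifelse(ls$focal_position %in% b$dam$focal_position, 1, 0)
  rn <- simulate_reads(b$genome, ls, coverage = 50, seed = 31)
  en <- simulate_signals(rn, signal_model(delta_6mA = 1.5),
                         site_modifications = b$mods, positions = b$positions,
                         seed = 32)
  d <- difference_table(en, b$events_wga, 5)
  regions <- extract_candidate_regions(d, b$genome,
                                       subsample_bp = min(10000, nrow(d)),
                                       top_n = 300, flank = 10, seed = 33)
  hits <- sum(Biostrings::vcountPattern("GATC", regions) > 0)
  # base rate of a GATC in a 21-bp window is ~ 18/256
  base_rate <- 18 / 256
  expect_gt((hits / 300) / base_rate, 3)
})

test_that("site-call BED and null TSV exports are well formed", {
  d <- mk_diff(c(99, 100, 101), c(0.001, 0.5, 0.9))
  nul <- build_null(d, positions = 100L, region_end = 200)
  calls <- classify_sites(tibble(motif = "DAM", start = 98L, strand = "+",
                                 focal_position = 100L), d, nul, "c1")
  bed_path <- withr::local_tempfile(fileext = ".bed")
  write_site_calls_bed(calls, bed_path)
  bed <- utils::read.table(bed_path, sep = "\t")
  expect_equal(ncol(bed), 8)
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 101)

  null_path <- withr::local_tempfile(fileext = ".tsv")
  write_null_tsv(nul, null_path)
  first <- readLines(null_path, n = 1)
  expect_match(first, "^# threshold")
})
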