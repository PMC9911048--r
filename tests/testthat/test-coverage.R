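test_that("target_coverage follows the nearest-rank-lower rule on pooled windows", {
  mk_track <- function(values) {
    tibble(window_index = seq_along(values) - 1L,
           window_start = (seq_along(values) - 1L) * 10000L,
           window_end = seq_along(values) * 10000L,
           coverage = values)
  }
  expect_equal(target_coverage(mk_track(rep(100, 20)), 5), 100)
  expect_equal(target_coverage(mk_track(1:100), 5), 5)
  expect_equal(target_coverage(list(mk_track(rep(50, 10)),
                                    mk_track(rep(100, 10))), 5), 50)
  # per-group pooling (e.g. a low-coverage late time point pooled separately)
  grp <- target_coverage(list(mk_track(rep(100, 10)), mk_track(rep(20, 10))),
                         5, groups = c("main", "late"))
  expect_equal(unname(grp["late"]), 20)
  expect_equal(unname(grp["main"]), 100)
  expect_error(target_coverage(list()), "at least one")
})

test_that("reads_per_window implements the coverage-standardization formula", {
  expect_equal(reads_per_window(100, 10000, 2000), 500L)
  expect_equal(reads_per_window(0, 10000, 2000), 0L)
  expect_equal(reads_per_window(50, 10000, 2500), 200L)
  expect_error(reads_per_window(50, 10000, 0), "positive")
})

test_that("coverage_track averages per-base depth within windows", {
  # two reads covering [0, 50) and [25, 75) of a 100 bp genome, window 50
  r <- structure(
    tibble(read_id = c("a", "b"), sample = "wga",
           start = c(0L, 25L), length = c(50L, 50L)),
    genome_length = 100L, class = c("read_set", class(tibble())))
  tr <- coverage_track(r, 100, window = 50)
  expect_equal(tr$coverage, c((50 + 25) / 50, 25 / 50))
})

test_that("subsampling hits a 50x target from a 100x pool in one pass", {
  g <- generate_genome(2e5, 0.5, seed = 1)
  pool <- simulate_reads(g, NULL, coverage = 100, read_length_mean = 2000,
                         seed = 2)
  res <- subsample(pool, 50, window = 10000, seed = 3)
  realized <- coverage_track(res$reads, 2e5, 10000)$coverage
  expect_lt(median(abs(realized - 50) / 50), 0.1)
  expect_equal(res$plan$iterations_used, 1)
  # subset, never duplicated
  expect_true(all(res$reads$read_id %in% pool$read_id))
  expect_false(any(duplicated(res$reads$read_id)))
})

test_that("a target equal to the pool coverage keeps (nearly) all reads", {
  g <- generate_genome(1e5, 0.5, seed = 4)
  pool <- simulate_reads(g, NULL, coverage = 40, read_length_mean = 2000,
                         seed = 5)
  res <- suppressWarnings(subsample(pool, sum(pool$length) / 1e5, tol = 1,
                                    window = 10000, seed = 6))
  expect_equal(res$plan$iterations_used, 1)
  expect_gt(nrow(res$reads) / nrow(pool), 0.9)
})

test_that("bimodal read lengths trigger the resampling loop", {
  glen <- 2e5
  withr::with_seed(7, {
    n <- 600
    lens <- sample(c(1000L, 9000L), n, replace = TRUE)
    pool <- structure(
      tibble(read_id = paste0("r", 1:n), sample = "wga",
             start = as.integer(floor(runif(n, 0, glen - 9000))),
             length = lens),
      genome_length = as.integer(glen),
      class = c("read_set", class(tibble())))
  })
  errs <- c()
  res <- withCallingHandlers(
    subsample(pool, 10, window = 2000, tol = 0.1, max_iter = 5, seed = 8),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_gte(res$plan$iterations_used, 2)
  # the returned iterate is the best one, so its error cannot exceed a
  # single-draw first-iteration error with the same seed
  first <- withCallingHandlers(
    subsample(pool, 10, window = 2000, tol = 0.1, max_iter = 1, seed = 8),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_lte(res$plan$median_rel_error, first$plan$median_rel_error)
})

test_that("subsample is deterministic and partitions reads by start window", {
  g <- generate_genome(1e5, 0.5, seed = 9)
  pool <- simulate_reads(g, NULL, coverage = 60, read_length_mean = 2000,
                         seed = 10)
  a <- subsample(pool, 30, window = 10000, seed = 11)
  b <- subsample(pool, 30, window = 10000, seed = 11)
  expect_equal(as_tibble(a$reads), as_tibble(b$reads))
  expect_equal(glance(a$plan), glance(b$plan))
  # monotonicity of realized genome-wide coverage in the target
  c20 <- sum(subsample(pool, 20, window = 10000, seed = 12)$reads$length)
  c40 <- sum(subsample(pool, 40, window = 10000, seed = 12)$reads$length)
  expect_lte(c20, c40)
  # every selected read's start is inside a window that requested reads
  plan <- tidy(a$plan)
  widx <- a$reads$start %/% 10000L
  expect_true(all(widx %in% plan$window_index[plan$n_requested > 0]))
})

test_that("subsample refuses an unreachable target", {
  g <- generate_genome(5e4, 0.5, seed = 13)
  pool <- simulate_reads(g, NULL, coverage = 10, read_length_mean = 2000,
                         seed = 14)
  expect_error(subsample(pool, 50, seed = 15), "below the target")
})
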