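# build a sites + calls pair whose per-window methylated fractions are given
# exactly: `n_per` sites per window, `round(frac * n_per)` of them methylated
fractions_fixture <- function(fracs, window = 1000L, n_per = 20L,
                              motif = "DAM", condition = "c1") {
  nw <- length(fracs)
  site_pos <- as.integer(unlist(lapply(seq_len(nw) - 1L, function(i) {
    i * window + seq_len(n_per) * (window %/% (n_per + 1L))
  })))
  sites <- tibble(motif = motif, start = site_pos, strand = "+",
                  focal_position = site_pos)
  meth <- unlist(lapply(seq_len(nw), function(i) {
    k <- round(fracs[i] * n_per)
    rep(c(TRUE, FALSE), c(k, n_per - k))
  }))
  calls <- structure(
    tibble(condition = condition, motif = motif, start = site_pos,
           strand = "+", focal_position = site_pos,
           site_pvalue = ifelse(meth, 1e-6, 0.5), methylated = meth),
    class = c("site_calls", class(tibble())))
  list(sites = sites, calls = calls, genome_length = nw * window,
       window = window)
}

test_that("window fractions: arithmetic, zero-site exclusion, tiling count", {
  fx <- fractions_fixture(c(0.25, 0.5), window = 10000L, n_per = 40L)
  prof <- window_fractions(fx$calls, fx$sites, fx$genome_length, 10000L)
  expect_equal(prof$n_sites, c(40L, 40L))
  expect_equal(prof$fraction, c(0.25, 0.5))

  # a 5 Mbp genome tiles into 500 10-Kbp windows (before exclusion)
  prof5 <- window_fractions(fx$calls, fx$sites, 5e6, 10000L)
  excluded <- attr(prof5, "excluded_windows")
  expect_equal(nrow(prof5) + nrow(excluded), 500)
  expect_equal(nrow(prof5), 2)      # only two windows contain sites
  expect_false(any(excluded$window_index %in% prof5$window_index))
  expect_error(window_fractions(fx$calls, fx$sites, 1e5, 0), "positive")
})

test_that("weighted-mean conservation holds exactly", {
  b <- sim_bundle(genome_len = 1e5, coverage = 30, seed = 60)
  calls <- classify_sites(rbind(b$dam, b$dcm), b$diff, b$null, "c1")
  prof <- window_fractions(calls, rbind(b$dam, b$dcm), 1e5, 10000L)
  for (m in c("DAM", "DCM")) {
    pm <- prof[prof$motif == m, ]
    sites_m <- if (m == "DAM") b$dam else b$dcm
    expect_equal(sum(pm$n_methylated) / sum(pm$n_sites),
                 sum(calls$methylated[calls$motif == m]) / nrow(sites_m))
  }
})

test_that("normalization divides by the mean included fraction", {
  fx <- fractions_fixture(c(0.5, 1.0), window = 10000L, n_per = 40L)
  prof <- window_fractions(fx$calls, fx$sites, fx$genome_length, 10000L)
  norm <- normalize_profile(prof)
  expect_equal(norm$fraction, c(2 / 3, 4 / 3))
  expect_equal(mean(norm$fraction), 1, tolerance = 1e-12)

  const <- fractions_fixture(c(0.5, 0.5, 0.5), n_per = 40L)
  nc <- normalize_profile(window_fractions(const$calls, const$sites,
                                           const$genome_length, 1000L))
  expect_equal(nc$fraction, rep(1, 3))

  zero <- fractions_fixture(c(0, 0), n_per = 40L)
  zp <- window_fractions(zero$calls, zero$sites, zero$genome_length, 1000L)
  expect_error(normalize_profile(zp), "all-zero")
})

test_that("pearson matches hand computation and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, c(4, 3, 2, 1))$r, -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("partial correlation reduces to pearson and hits the closed form", {
  withr::with_seed(1, {
    x <- rnorm(50); y <- rnorm(50)
  })
  a <- partial_correlation(x, y)
  b <- pearson(x, y)
  expect_equal(a$r, b$r)
  expect_equal(a$pvalue, b$pvalue)

  # exact sample correlations 0.5 between x, y, z -> partial r = 1/3
  n <- 40
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  withr::with_seed(2, {
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  })
  X <- Q %*% chol(R)
  expect_equal(cor(X[, 1], X[, 2]), 0.5, tolerance = 1e-12)
  res <- partial_correlation(X[, 1], X[, 2], list(z = X[, 3]))
  expect_equal(res$r, 1 / 3, tolerance = 1e-10)
  expect_equal(res$df, n - 3)

  # residualizing y on itself leaves nothing to correlate
  expect_error(partial_correlation(x, y, list(z = y)), "zero residual")
  # collinear covariates are named
  expect_error(partial_correlation(x, y, list(a = x + 1, b = 2 * x + 2)),
               "collinear")
})

test_that("pairwise condition matrix: pair count, self-pairs, shared windows", {
  fx <- lapply(1:6, function(i) {
    f <- fractions_fixture(seq(0.1, 0.9, length.out = 30) + i * 0.001,
                           condition = paste0("c", i))
    window_fractions(f$calls, f$sites, f$genome_length, f$window)
  })
  names(fx) <- paste0("c", 1:6)
  cm <- pairwise_condition_matrix(fx, covariates = "none")
  expect_equal(nrow(cm), choose(6, 2))
  expect_equal(cm$covariates, rep("none", 15))

  # identical call sets correlate perfectly
  same <- pairwise_condition_matrix(fx[c(1, 1)], covariates = "none")
  expect_equal(same$r, 1)

  # fewer than 3 shared windows -> NA with a warning
  tiny_a <- fx[[1]][1:2, ]
  tiny_b <- fx[[2]][1:2, ]
  expect_warning(
    cm2 <- pairwise_condition_matrix(list(a = tiny_a, b = tiny_b),
                                     covariates = "none"),
    "shared windows")
  expect_true(is.na(cm2$r))
})

test_that("replicate pairs out-correlate cross pairs under controlled sharing", {
  nw <- 100
  wins <- 0
  for (s in 1:100) {
    withr::with_seed(3000 + s, {
      shared <- rbeta(nw, 2, 2)
      mkfrac <- function(w) pmin(1, pmax(0, w * shared + (1 - w) * rbeta(nw, 2, 2)))
      profs <- list(rep1 = mkfrac(0.9), rep2 = mkfrac(0.9), other = mkfrac(0.3))
    })
    fx <- purrr::imap(profs, function(f, nm) {
      z <- fractions_fixture(f, n_per = 40L, condition = nm)
      window_fractions(z$calls, z$sites, z$genome_length, z$window)
    })
    cm <- pairwise_condition_matrix(fx, covariates = "none")
    r_rep <- cm$r[cm$condition_a == "rep1" & cm$condition_b == "rep2"]
    r_cross <- max(cm$r[cm$condition_b == "other" | cm$condition_a == "other"])
    if (r_rep > r_cross) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("long-range scan: self-lag unity, i.i.d. null, planted periodicity", {
  # i.i.d. fractions: no correlation at any separation
  withr::with_seed(4, {
    fx <- fractions_fixture(runif(250, 0.2, 0.8), window = 1000L, n_per = 20L)
  })
  grid <- long_range_scan(fx$calls, fx$sites, fx$genome_length,
                          window_sizes = 1000L,
                          separations = c(-1000L, 0L, 5000L, 20000L))
  self <- grid[grid$separation == -1000L, ]
  expect_equal(self$r, 1)
  iid <- grid[grid$separation >= 0, ]
  expect_true(all(iid$n_pairs >= 200))
  expect_true(all(abs(iid$r) < 0.1))

  # planted period of 10 windows: local max near separation (P-1)*w
  period <- 10
  fr <- 0.5 + 0.4 * sin(2 * pi * (0:249) / period)
  fx2 <- fractions_fixture(fr, window = 1000L, n_per = 40L)
  seps <- seq(0L, 15000L, by = 1000L)
  g2 <- long_range_scan(fx2$calls, fx2$sites, fx2$genome_length,
                        window_sizes = 1000L, separations = seps)
  peak_sep <- g2$separation[which.max(g2$r)]
  expect_equal(peak_sep, (period - 1) * 1000L)
})

test_that("profile export formats are consistent", {
  fx <- fractions_fixture(c(0.25, 0.75), window = 10000L, n_per = 40L)
  prof <- window_fractions(fx$calls, fx$sites, fx$genome_length, 10000L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_window_profile_tsv(prof, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$fraction, prof$fraction)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_window_profile_bedgraph(prof, bg)
  expect_equal(ncol(utils::read.table(bg, sep = "\t")), 4)
})
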