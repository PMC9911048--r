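test_that("position_test matches hand-enumerable cases", {
  # all native below all wga: U = 0, two-sided p = 2/20
  res <- position_test(c(10.1, 10.2, 10.3), c(11.1, 11.2, 11.4))
  expect_equal(res$u_pvalue, 0.1)
  expect_lt(res$mean_diff, 0)

  # identical multisets: no evidence, mean_diff exactly 0
  res <- position_test(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(res$u_pvalue, 1)
  expect_equal(res$mean_diff, 0)

  # zero-variance conventions for the t test
  expect_equal(position_test(c(5, 5, 5), c(5, 5, 5))$t_pvalue, 1)
  expect_equal(position_test(c(5, 5, 5), c(6, 6, 6))$t_pvalue,
               .Machine$double.eps)
  expect_error(position_test(numeric(0), 1:3), "coverage")
})

test_that("U p-value equals the exhaustive-enumeration oracle for n, m <= 8", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      n <- sample(2:8, 1)
      m <- sample(2:8, 1)
      # half the draws rounded to force ties, including cross-group ties
      x <- round(rnorm(n, 0, 2), sample(0:1, 1))
      y <- round(rnorm(m, 0.5, 2), sample(0:1, 1))
      expect_equal(position_test(x, y)$u_pvalue, oracle_u_pvalue(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("normal-approximation branch agrees with wilcox.test", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      n <- sample(9:40, 1)
      m <- sample(9:40, 1)
      x <- rnorm(n)
      y <- rnorm(m, 0.3)
      ours <- position_test(x, y)$u_pvalue
      ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-10)
      # with heavy ties the tie-corrected variance must match too
      xt <- round(x); yt <- round(y)
      ref_t <- suppressWarnings(
        stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value)
      expect_equal(position_test(xt, yt)$u_pvalue, ref_t, tolerance = 1e-10)
    }
  })
})

test_that("swapping samples negates mean_diff and preserves both p-values", {
  withr::with_seed(44, {
    for (rep in 1:15) {
      x <- rnorm(sample(3:30, 1))
      y <- rnorm(sample(3:30, 1), 0.5)
      a <- position_test(x, y)
      b <- position_test(y, x)
      expect_equal(a$mean_diff, -b$mean_diff)
      expect_equal(a$u_pvalue, b$u_pvalue, tolerance = 1e-12)
      expect_equal(a$t_pvalue, b$t_pvalue, tolerance = 1e-12)
    }
  })
})

test_that("difference_table enforces the coverage threshold and position grid", {
  ep <- null_event_pair(n_pos = 100, cov = 10, seed = 2)
  d <- difference_table(ep$native, ep$wga, min_cov = 5)
  expect_equal(nrow(d), 100)
  expect_equal(d$position, 0:99)
  expect_true(all(d$cov_native == 10 & d$cov_wga == 10))
  expect_true(all(d$u_pvalue >= 0 & d$u_pvalue <= 1))

  # drop one sample's observations at position 0 below min_cov
  nat_thin <- ep$native[!(ep$native$position == 0 &
                            seq_len(nrow(ep$native)) <= 6), ]
  d2 <- difference_table(nat_thin, ep$wga, min_cov = 5)
  expect_false(0 %in% d2$position)

  shifted <- dplyr::mutate(ep$wga, position = position + 1000L)
  expect_warning(d3 <- difference_table(ep$native, shifted), "disjoint")
  expect_equal(nrow(d3), 0)
})

test_that("difference_table matches position_test row by row", {
  ep <- null_event_pair(n_pos = 40, cov = 7, seed = 3)  # exercises exact branch
  d <- difference_table(ep$native, ep$wga, min_cov = 5)
  for (p in c(0, 17, 39)) {
    ref <- position_test(ep$native$signal[ep$native$position == p],
                         ep$wga$signal[ep$wga$position == p])
    row <- d[d$position == p, ]
    expect_equal(row$u_pvalue, ref$u_pvalue, tolerance = 1e-12)
    expect_equal(row$t_pvalue, ref$t_pvalue, tolerance = 1e-12)
    expect_equal(row$mean_diff, ref$mean_diff, tolerance = 1e-12)
  }
})

test_that("null p-values are calibrated at the usual alpha levels", {
  ep <- null_event_pair(n_pos = 4000, cov = 30, seed = 4)
  d <- difference_table(ep$native, ep$wga, min_cov = 5)
  for (alpha in c(0.01, 0.05, 0.1)) {
    frac <- mean(d$u_pvalue < alpha)
    expect_lt(abs(frac - alpha), 3 * sqrt(alpha * (1 - alpha) / 4000) + 1e-9)
  }
})

test_that("median p at a fully methylated site falls with coverage", {
  meds <- vapply(c(10, 25, 50), function(cov) {
    withr::with_seed(1000 + cov, {
      p <- vapply(1:300, function(i) {
        position_test(rnorm(cov, 0.5), rnorm(cov, 0))$u_pvalue
      }, numeric(1))
      median(p)
    })
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("summarize_titration validates its grid and orders quartiles", {
  mk_diff <- function(p) {
    structure(tibble(position = seq_along(p) - 1L, cov_native = 10L,
                     cov_wga = 10L, mean_diff = 0, u_pvalue = p,
                     t_pvalue = p),
              class = c("difference_table", class(tibble())))
  }
  tabs <- list("0" = mk_diff(runif(50)), "1" = mk_diff(runif(50) / 100))
  ts <- summarize_titration(tabs, list(M = c(5L, 10L, 20L)))
  expect_equal(nrow(ts), 2)
  expect_true(all(ts$p_q25 <= ts$p_median & ts$p_median <= ts$p_q75))
  expect_lt(ts$p_median[ts$fraction_native == 1],
            ts$p_median[ts$fraction_native == 0])
  expect_error(summarize_titration(tabs["1"], list(M = 1L)), "include 0 and 1")
})

test_that("difference-table TSV round-trips", {
  ep <- null_event_pair(n_pos = 30, cov = 10, seed = 5)
  d <- difference_table(ep$native, ep$wga)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_difference_table_tsv(d, path)
  expect_equal(as_tibble(read_difference_table_tsv(path)), as_tibble(d),
               tolerance = 1e-12)
})
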