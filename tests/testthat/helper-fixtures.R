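# Independent exact oracle for the two-sided Mann-Whitney U p-value:
# enumerates every assignment of group labels to the pooled observations and
# counts pairwise wins directly (no ranks), so it shares no code path with the
# package's rank-sum implementation.
oracle_u_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  picks <- combn(n1 + n2, n1)
  u_all <- apply(picks, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# One shared small simulation: genome, Dam/Dcm sites, landscape with a given
# constant theta, native + wga event tables restricted to motif +/- 1 and
# pre-drawn null positions, the difference table and the null distribution.
sim_bundle <- function(genome_len = 2e5, coverage = 50, theta = NULL,
                       rho = 0.8, n_null = 1000, model = signal_model(),
                       seed = 1000) {
  g <- generate_genome(genome_len, 0.5, seed = seed)
  dam <- scan_motifs(g, motif_dam())
  dcm <- scan_motifs(g, motif_dcm())
  foc <- sort(c(dam$focal_position, dcm$focal_position))
  ls <- build_landscape(g, foc, "c1", rho = rho, seed = seed + 1)
  if (!is.null(theta)) ls$theta <- theta
  rn <- simulate_reads(g, ls, coverage = coverage, seed = seed + 2)
  rw <- simulate_reads(g, NULL, coverage = coverage, seed = seed + 3)
  null_pos <- withr::with_seed(seed + 4,
    sort(sample(0:(min(genome_len, 1e6) - 1L), n_null)))
  pos <- sort(unique(c(outer(c(foc, null_pos), -1:1, `+`))))
  pos <- pos[pos >= 0 & pos < genome_len]
  mods <- stats::setNames(c(rep("6mA", nrow(dam)), rep("5mC", nrow(dcm))),
                          c(dam$focal_position, dcm$focal_position))
  en <- simulate_signals(rn, model, site_modifications = mods,
                         positions = pos, seed = seed + 5)
  ew <- simulate_signals(rw, model, site_modifications = mods,
                         positions = pos, seed = seed + 6)
  d <- difference_table(en, ew, min_cov = 5)
  nul <- build_null(d, positions = null_pos, region_end = min(genome_len, 1e6))
  list(genome = g, genome_len = genome_len, dam = dam, dcm = dcm,
       landscape = ls, reads_native = rn, reads_wga = rw,
       events_native = en, events_wga = ew, diff = d, null = nul,
       null_pos = null_pos, mods = mods, positions = pos)
}

# Event table with i.i.d. Gaussian signals at each of `n_pos` positions in
# both samples: the no-difference null for calibration checks.
null_event_pair <- function(n_pos = 5000, cov = 30, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(label) {
      tibble::tibble(
        position = rep(seq_len(n_pos) - 1L, each = cov),
        read_id = paste0(label, seq_len(n_pos * cov)),
        sample = label,
        signal = rnorm(n_pos * cov)
      )
    }
    list(native = mk("a"), wga = mk("b"))
  })
}
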