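#' Simulate a per-site methylation landscape for one or more conditions
#'
#' Ground truth for the simulator: every motif site gets, per condition, a
#' probability `theta` that any single molecule is methylated there. Spatial
#' structure is imposed at the window level: each condition's per-window base
#' level is a mixture `rho * shared + (1 - rho) * condition-specific`, with both
#' profiles drawn i.i.d. from `Beta(beta_shape1, beta_shape2)` per window.
#' `rho = 1` makes all conditions share identical base levels; `rho = 0` makes
#' them independent. Site-level theta is the window base level plus clipped
#' Gaussian noise, emulating genomes in which particular regions are
#' consistently hyper- or hypo-methylated, with condition dependence.
#'
#' @param genome A genome, or a plain genome length in bases.
#' @param sites Integer vector of motif focal positions (0-based), e.g.
#'   `scan_motifs(g, motif_dam())$focal_position`.
#' @param conditions Character vector of condition labels (≥ 1).
#' @param window Window width in bases over which base levels are constant
#'   (default 10,000).
#' @param rho Shared-profile weight in `[0, 1]`.
#' @param beta_shape1,beta_shape2 Beta parameters of the window base-level
#'   distribution (default `Beta(2, 2)`: mean 0.5, moderate spread).
#' @param site_sd Standard deviation of the clipped site-level noise
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A tibble of class `"methylation_landscape"` with columns
#'   `condition`, `focal_position`, `window_index`, `theta`; the per-window
#'   base levels are in `attr(, "base_levels")` and the generator parameters in
#'   `attr(, "params")`.
#' @export
build_landscape <- function(genome, sites, conditions, window = 10000L,
                            rho = 0.5, beta_shape1 = 2, beta_shape2 = 2,
                            site_sd = 0.05, seed = NULL) {
  glen <- if (is.numeric(genome) && length(genome) == 1) as.integer(genome)
          else genome_length(genome)
  if (length(sites) == 0) abort("`sites` must contain at least one focal position")
  if (any(sites < 0 | sites >= glen)) abort("`sites` must lie within the genome")
  check_fraction(rho, "rho")
  if (length(conditions) < 1) abort("at least one condition label is required")
  sites <- sort(as.integer(sites))
  n_windows <- nrow(genome_windows(glen, window))

  with_seed_if(seed, {
    shared <- rbeta(n_windows, beta_shape1, beta_shape2)
    base_levels <- purrr::map_dfr(conditions, function(cond) {
      own <- rbeta(n_windows, beta_shape1, beta_shape2)
      tibble(condition = cond,
             window_index = seq_len(n_windows) - 1L,
             base_level = rho * shared + (1 - rho) * own)
    })
    widx <- window_index(sites, window)
    theta_tbl <- purrr::map_dfr(conditions, function(cond) {
      bl <- base_levels$base_level[base_levels$condition == cond][widx + 1L]
      tibble(condition = cond,
             focal_position = sites,
             window_index = widx,
             theta = pmin(1, pmax(0, bl + rnorm(length(sites), 0, site_sd))))
    })
    structure(
      theta_tbl,
      base_levels = base_levels,
      params = list(window = as.integer(window), rho = rho,
                    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                    site_sd = site_sd, seed = seed,
                    genome_length = glen),
      class = c("methylation_landscape", class(theta_tbl))
    )
  })
}

# theta lookup for one condition as a named-position vector
landscape_theta <- function(landscape, condition) {
  sub <- landscape[landscape$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("condition '%s' not present in the landscape", condition))
  }
  stats::setNames(sub$theta, sub$focal_position)
}

#' @export
print.methylation_landscape <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<methylation_landscape: %d sites x %d condition(s), window %d bp, rho %.2f>\n",
    length(unique(x$focal_position)), length(unique(x$condition)),
    p$window, p$rho))
  NextMethod()
}
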