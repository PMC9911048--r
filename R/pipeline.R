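default_config <- function() {
  list(
    genome = list(path = NULL, length = 500000, gc = 0.5, contig_id = "contig_1"),
    motifs = list(
      list(name = "DAM", iupac = "GATC", offset = 1, modification = "6mA"),
      list(name = "DCM", iupac = "CCWGG", offset = 1, modification = "5mC")
    ),
    conditions = list(list(label = "condition_1", coverage = 25)),
    landscape = list(rho = 0.5, window = 10000, beta_shape1 = 2,
                     beta_shape2 = 2, site_sd = 0.05),
    wga = list(coverage = 25),
    reads = list(length_mean = 5000),
    signal = list(sigma = 1.0, delta_6mA = 0.5, delta_5mC = 1.2,
                  halfwidth_k = 2),
    subsample = list(enabled = FALSE, percentile = 5, window = 10000,
                     tol = 0.1, max_iter = 5),
    diff = list(min_cov = 5, targeted = TRUE),
    null = list(n_sites = 1000, region_end = 1000000, percentile = 10),
    windows = list(window = 10000),
    titration = list(enabled = FALSE,
                     fractions = c(0, 0.25, 0.5, 0.75, 1),
                     coverage = 25),
    scan = list(enabled = FALSE,
                window_sizes = c(1000, 10000, 50000),
                separations = c(0, 10000, 100000)),
    seed = NULL,
    outdir = NULL
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (nm %in% c("motifs", "conditions")) {
      base[[nm]] <- user[[nm]]
    } else if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills in defaults (10-Kbp windows, 10th
#' null percentile, 1-Mbp null region, titration fractions
#' `{0, 0.25, 0.5, 0.75, 1}`, Dam/Dcm motifs, ...) and checks every field,
#' reporting all problems at once with their field paths.
#'
#' @param config Path to a YAML document, or a named list.
#' @return The completed config (class `"run_config"`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  problems <- character(0)
  if (length(unknown) > 0) {
    problems <- c(problems,
                  sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- merge_config(base, config[setdiff(names(config), unknown)])

  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  if (is.null(cfg$genome$path)) {
    chk(is.numeric(cfg$genome$length) && cfg$genome$length > 0,
        "genome.length: must be a positive number of bases")
    chk(is.numeric(cfg$genome$gc) && cfg$genome$gc >= 0 && cfg$genome$gc <= 1,
        "genome.gc: must lie in [0, 1]")
    chk(!is.null(cfg$seed), "seed: mandatory for simulate-backed runs")
  } else {
    chk(file.exists(cfg$genome$path),
        sprintf("genome.path: file '%s' does not exist", cfg$genome$path))
  }
  chk(length(cfg$motifs) >= 1, "motifs: at least one motif is required")
  chk(length(cfg$conditions) >= 1, "conditions: at least one condition is required")
  for (cc in cfg$conditions) {
    chk(is.numeric(cc$coverage) && cc$coverage > 0,
        sprintf("conditions[%s].coverage: must be > 0", cc$label %||% "?"))
  }
  chk(is.numeric(cfg$landscape$rho) && cfg$landscape$rho >= 0 &&
        cfg$landscape$rho <= 1, "landscape.rho: must lie in [0, 1]")
  chk(cfg$null$percentile >= 0 && cfg$null$percentile <= 100,
      "null.percentile: must lie in [0, 100]")
  chk(cfg$null$n_sites > 0, "null.n_sites: must be > 0")
  chk(cfg$windows$window > 0, "windows.window: must be > 0")
  chk(cfg$subsample$percentile >= 0 && cfg$subsample$percentile <= 100,
      "subsample.percentile: must lie in [0, 100]")
  chk(cfg$signal$sigma > 0, "signal.sigma: must be > 0")
  fr <- cfg$titration$fractions
  chk(all(fr >= 0 & fr <= 1), "titration.fractions: must lie in [0, 1]")
  chk(any(fr == 0) && any(fr == 1),
      "titration.fractions: the grid must include 0 and 1 (required by the titration summary)")

  if (length(problems) > 0) {
    abort(paste(c("invalid configuration:", problems), collapse = "\n  - "))
  }
  structure(cfg, class = c("run_config", "list"))
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate → (subsample) → diff → call → compare, plus optional
#' titration and long-range-scan stages, writing every primary table under
#' `config$outdir`. A stage whose parameter hash matches the previous run and
#' whose outputs still exist is skipped unless `force = TRUE`; a rerun with an
#' identical config and seed reproduces byte-identical primary tables.
#'
#' By default signals are simulated in targeted mode: events are emitted only
#' at motif focal positions ±1 and at the pre-drawn null positions ±1, which is
#' what the downstream site classification consumes (`diff.targeted: false`
#' emits the full event table).
#'
#' @param config A [validate_config()] result, a list, or a YAML path.
#' @param force Re-run stages even when up to date.
#' @return A tibble manifest (stage, output, params_hash, status), invisibly
#'   written to `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (is.null(cfg$outdir)) abort("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  hash_file <- file.path(cfg$outdir, "run_hashes.yaml")
  old_hashes <- if (file.exists(hash_file)) yaml::read_yaml(hash_file) else list()
  new_hashes <- list()
  manifest <- list()
  out_path <- function(...) file.path(cfg$outdir, paste0(...))

  motifs <- purrr::map(cfg$motifs, ~ motif_definition(.x$name, .x$iupac,
                                                      .x$offset, .x$modification))
  cond_labels <- purrr::map_chr(cfg$conditions, "label")
  model <- signal_model(sigma = cfg$signal$sigma,
                        delta_6mA = cfg$signal$delta_6mA,
                        delta_5mC = cfg$signal$delta_5mC,
                        halfwidth_k = cfg$signal$halfwidth_k,
                        baseline_seed = seed + 7L)

  prev_hash <- ""
  stage_ready <- function(stage, params, outputs) {
    h <- rlang::hash(list(stage, params, prev_hash))
    prev_hash <<- h
    new_hashes[[stage]] <<- h
    up_to_date <- !force && identical(old_hashes[[stage]], h) &&
      all(file.exists(outputs))
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, output = paste(basename(outputs), collapse = ";"),
      params_hash = h,
      status = if (up_to_date) "skipped" else "completed")
    up_to_date
  }

  # ---- simulate -----------------------------------------------------------
  sim_outputs <- c(out_path("genome.fasta"), out_path("landscape.tsv"),
                   out_path("reads_wga.tsv"),
                   out_path("reads_", cond_labels, ".tsv"))
  sim_params <- cfg[c("genome", "motifs", "conditions", "landscape", "wga",
                      "reads", "seed")]
  if (stage_ready("simulate", sim_params, sim_outputs)) {
    stage_log("simulate", "up to date, skipping")
    genome <- read_genome_fasta(out_path("genome.fasta"))
    glen <- genome_length(genome)
    sites <- purrr::map(motifs, ~ scan_motifs(genome, .x))
    names(sites) <- purrr::map_chr(motifs, "name")
    reads_nat <- purrr::map(cond_labels, ~ read_read_set_tsv(
      out_path("reads_", .x, ".tsv"), glen))
    names(reads_nat) <- cond_labels
    reads_wga <- read_read_set_tsv(out_path("reads_wga.tsv"), glen)
  } else {
    stage_log("simulate", "running")
    genome <- if (!is.null(cfg$genome$path)) {
      read_genome_fasta(cfg$genome$path)
    } else {
      generate_genome(cfg$genome$length, cfg$genome$gc, seed = seed,
                      contig_id = cfg$genome$contig_id)
    }
    glen <- genome_length(genome)
    write_genome_fasta(genome, out_path("genome.fasta"))
    sites <- purrr::map(motifs, ~ scan_motifs(genome, .x))
    names(sites) <- purrr::map_chr(motifs, "name")
    all_focal <- sort(unique(unlist(purrr::map(sites, "focal_position"))))
    landscape <- build_landscape(glen, all_focal, cond_labels,
                                 window = cfg$landscape$window,
                                 rho = cfg$landscape$rho,
                                 beta_shape1 = cfg$landscape$beta_shape1,
                                 beta_shape2 = cfg$landscape$beta_shape2,
                                 site_sd = cfg$landscape$site_sd,
                                 seed = seed + 11L)
    write_table_tsv(as_tibble(landscape), out_path("landscape.tsv"))
    reads_nat <- purrr::map(seq_along(cond_labels), function(i) {
      r <- simulate_reads(genome, landscape, condition = cond_labels[i],
                          coverage = cfg$conditions[[i]]$coverage,
                          read_length_mean = cfg$reads$length_mean,
                          id_prefix = paste0("nat_", cond_labels[i]),
                          seed = seed + 100L + i)
      write_read_set_tsv(r, out_path("reads_", cond_labels[i], ".tsv"),
                         cfg$genome$contig_id)
      r
    })
    names(reads_nat) <- cond_labels
    reads_wga <- simulate_reads(genome, NULL, coverage = cfg$wga$coverage,
                                read_length_mean = cfg$reads$length_mean,
                                seed = seed + 200L)
    write_read_set_tsv(reads_wga, out_path("reads_wga.tsv"),
                       cfg$genome$contig_id)
    stage_log("simulate", sprintf("%d bp genome, %d condition(s), %d wga reads",
                                  glen, length(cond_labels), nrow(reads_wga)))
  }

  # ---- subsample (optional) ----------------------------------------------
  if (isTRUE(cfg$subsample$enabled)) {
    ss_outputs <- c(out_path("reads_wga.sub.tsv"),
                    out_path("reads_", cond_labels, ".sub.tsv"))
    if (stage_ready("subsample", cfg$subsample, ss_outputs)) {
      stage_log("subsample", "up to date, skipping")
      reads_nat <- purrr::map(cond_labels, ~ read_read_set_tsv(
        out_path("reads_", .x, ".sub.tsv"), glen))
      names(reads_nat) <- cond_labels
      reads_wga <- read_read_set_tsv(out_path("reads_wga.sub.tsv"), glen)
    } else {
      stage_log("subsample", "running")
      tracks <- purrr::map(c(reads_nat, list(wga = reads_wga)),
                           coverage_track, genome_length = glen,
                           window = cfg$subsample$window)
      tgt <- target_coverage(tracks, cfg$subsample$percentile)
      stage_log("subsample", sprintf("target %.1fx", tgt))
      reads_nat <- purrr::map(cond_labels, function(cl) {
        res <- subsample(reads_nat[[cl]], tgt, glen,
                         window = cfg$subsample$window,
                         tol = cfg$subsample$tol,
                         max_iter = cfg$subsample$max_iter,
                         seed = seed + 300L)
        write_read_set_tsv(res$reads, out_path("reads_", cl, ".sub.tsv"))
        res$reads
      })
      names(reads_nat) <- cond_labels
      res_w <- subsample(reads_wga, tgt, glen, window = cfg$subsample$window,
                         tol = cfg$subsample$tol,
                         max_iter = cfg$subsample$max_iter, seed = seed + 301L)
      reads_wga <- res_w$reads
      write_read_set_tsv(reads_wga, out_path("reads_wga.sub.tsv"))
    }
  }

  # ---- diff + call --------------------------------------------------------
  null_positions <- with_seed_if(seed + 400L, sort(sample(
    0:(min(cfg$null$region_end, glen) - 1L), cfg$null$n_sites)))
  site_mods <- unlist(purrr::map(motifs, function(m) {
    f <- sites[[m$name]]$focal_position
    stats::setNames(rep(m$modification, length(f)), f)
  }))
  target_pos <- if (isTRUE(cfg$diff$targeted)) {
    focal <- unlist(purrr::map(sites, "focal_position"))
    sort(unique(c(outer(c(focal, null_positions), -1:1, `+`))))
  } else NULL
  target_pos <- target_pos[target_pos >= 0 & target_pos < glen]

  diff_outputs <- out_path("diff_", cond_labels, ".tsv")
  diff_params <- list(cfg$diff, cfg$signal, cfg$null, seed)
  diffs <- if (stage_ready("diff", diff_params, diff_outputs)) {
    stage_log("diff", "up to date, skipping")
    d <- purrr::map(cond_labels, ~ read_difference_table_tsv(
      out_path("diff_", .x, ".tsv")))
    names(d) <- cond_labels
    d
  } else {
    stage_log("diff", "running")
    ev_wga <- simulate_signals(reads_wga, model,
                               site_modifications = site_mods,
                               positions = target_pos, genome_length = glen,
                               seed = seed + 500L)
    d <- purrr::map(seq_along(cond_labels), function(i) {
      ev_nat <- simulate_signals(reads_nat[[i]], model,
                                 site_modifications = site_mods,
                                 positions = target_pos,
                                 genome_length = glen,
                                 seed = seed + 600L + i)
      dt <- difference_table(ev_nat, ev_wga, min_cov = cfg$diff$min_cov)
      write_difference_table_tsv(dt, out_path("diff_", cond_labels[i], ".tsv"))
      stage_log("diff", sprintf("%s: %d positions", cond_labels[i], nrow(dt)))
      dt
    })
    names(d) <- cond_labels
    d
  }

  call_outputs <- c(out_path("calls_", cond_labels, ".tsv"),
                    out_path("calls_", cond_labels, ".bed"),
                    out_path("null_", cond_labels, ".tsv"))
  calls <- if (stage_ready("call", c(diff_params, cfg$null), call_outputs)) {
    stage_log("call", "up to date, skipping")
    cl <- purrr::map(cond_labels, function(x) {
      tbl <- as_tibble(utils::read.table(out_path("calls_", x, ".tsv"),
                                         header = TRUE, sep = "\t"))
      structure(tbl, class = c("site_calls", class(tibble())))
    })
    names(cl) <- cond_labels
    cl
  } else {
    stage_log("call", "running")
    all_sites <- bind_rows(sites)
    cl <- purrr::map(cond_labels, function(x) {
      nul <- build_null(diffs[[x]], positions = null_positions,
                        region_end = cfg$null$region_end,
                        threshold_percentile = cfg$null$percentile,
                        genome_length = glen)
      write_null_tsv(nul, out_path("null_", x, ".tsv"))
      sc <- classify_sites(all_sites, diffs[[x]], nul, condition = x)
      write_site_calls_tsv(sc, out_path("calls_", x, ".tsv"))
      write_site_calls_bed(sc, out_path("calls_", x, ".bed"),
                           cfg$genome$contig_id)
      stage_log("call", sprintf("%s: %d sites, %.1f%% methylated", x,
                                nrow(sc), 100 * mean(sc$methylated)))
      sc
    })
    names(cl) <- cond_labels
    cl
  }

  # ---- compare ------------------------------------------------------------
  cmp_outputs <- c(out_path("profile_", cond_labels, ".tsv"),
                   if (length(cond_labels) >= 2) out_path("condition_matrix.tsv"))
  if (stage_ready("compare", c(diff_params, cfg$windows), cmp_outputs)) {
    stage_log("compare", "up to date, skipping")
  } else {
    stage_log("compare", "running")
    all_sites <- bind_rows(sites)
    profiles <- purrr::map(cond_labels, function(x) {
      tr <- list(
        native = coverage_track(reads_nat[[x]], glen, cfg$windows$window),
        wga = coverage_track(reads_wga, glen, cfg$windows$window)
      )
      pr <- window_fractions(calls[[x]], all_sites, glen,
                             window = cfg$windows$window,
                             coverage_tracks = tr)
      write_window_profile_tsv(pr, out_path("profile_", x, ".tsv"))
      pr
    })
    names(profiles) <- cond_labels
    if (length(cond_labels) >= 2) {
      cm <- pairwise_condition_matrix(profiles)
      write_table_tsv(cm, out_path("condition_matrix.tsv"))
    }
  }

  # ---- titrate (optional) -------------------------------------------------
  if (isTRUE(cfg$titration$enabled)) {
    ti_out <- out_path("titration.tsv")
    if (stage_ready("titrate", c(diff_params, cfg$titration), ti_out)) {
      stage_log("titrate", "up to date, skipping")
    } else {
      stage_log("titrate", "running")
      cl1 <- cond_labels[1]
      mix_pool <- simulate_reads(genome, NULL,
                                 coverage = cfg$titration$coverage + 5,
                                 read_length_mean = cfg$reads$length_mean,
                                 id_prefix = "wga_mix", seed = seed + 700L)
      ev_nat <- simulate_signals(reads_nat[[cl1]], model,
                                 site_modifications = site_mods,
                                 positions = target_pos, genome_length = glen,
                                 seed = seed + 701L)
      ev_mix <- simulate_signals(mix_pool, model,
                                 site_modifications = site_mods,
                                 positions = target_pos, genome_length = glen,
                                 seed = seed + 702L)
      ev_ctrl <- simulate_signals(reads_wga, model,
                                  site_modifications = site_mods,
                                  positions = target_pos, genome_length = glen,
                                  seed = seed + 703L)
      fr <- sort(cfg$titration$fractions)
      dtabs <- purrr::map(fr, function(f) {
        mixed <- mix_reads(reads_nat[[cl1]], mix_pool, f,
                           cfg$titration$coverage, seed = seed + 710L + round(100 * f))
        ev <- bind_rows(events_for_reads(ev_nat, mixed),
                        events_for_reads(ev_mix, mixed))
        difference_table(ev, ev_ctrl, min_cov = cfg$diff$min_cov)
      })
      names(dtabs) <- as.character(fr)
      tsum <- summarize_titration(dtabs, purrr::map(sites, "focal_position"))
      write_table_tsv(tsum, ti_out)
    }
  }

  # ---- scan (optional) ----------------------------------------------------
  if (isTRUE(cfg$scan$enabled)) {
    sc_out <- out_path("long_range_scan.tsv")
    if (stage_ready("scan", c(diff_params, cfg$scan), sc_out)) {
      stage_log("scan", "up to date, skipping")
    } else {
      stage_log("scan", "running")
      grids <- purrr::map_dfr(names(sites), function(mname) {
        cl <- calls[[1]][calls[[1]]$motif == mname, , drop = FALSE]
        g <- long_range_scan(cl, sites[[mname]], glen,
                             window_sizes = cfg$scan$window_sizes,
                             separations = cfg$scan$separations)
        mutate(g, motif = mname, .before = 1)
      })
      write_table_tsv(grids, sc_out)
    }
  }

  yaml::write_yaml(new_hashes, hash_file)
  manifest <- bind_rows(manifest)
  write_table_tsv(manifest, out_path("manifest.tsv"))
  invisible(manifest)
}
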