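#' Run configuration
#'
#' One nested list drives simulation and analysis.  Every default is the
#' study-standard value: 60-s sequences at 10 Hz with a deviant every 5th
#' item, 2-s fades, 8 task events, 2 x 2 conditions x 3 repetitions per
#' task, 68 channels at 1024 Hz, band-pass 0.1-100 Hz, -2..62 s segments
#' resampled to 512 Hz, 0.5-s cycle cropping, group threshold z > 3.1 and
#' individual threshold z > 1.64.  Override any entry via `...` using
#' nested lists, e.g. `fpvs_config(design = list(duration_s = 10))`.
#'
#' @param ... nested overrides merged over the defaults.
#' @return an object of class `fpvs_config`.
#' @export
fpvs_config <- function(...) {
  defaults <- list(
    n_participants = 2L,
    seed = 1L,
    design = list(duration_s = 60, f_base = 10, oddball_every = 5,
                  fade_in_s = 2, fade_out_s = 2, n_task_events = 8,
                  n_reps = 3, task_order = c("cross", "bars"),
                  n_words = 30, n_letters = 5),
    acquisition = list(fs_hz = 1024, pre_s = 2.5, post_s = 0.5),
    response = list(
      oddball_amps = c(0.15, 0.15, 0.20, 0.10), oddball_rh_ratio = 0.3,
      base_amps = c(2.0, 0.8, 0.4, 0.2)),
    noise = list(pink_exponent = 1, pink_scale = 1.4, alpha_amp = 0,
                 alpha_freq_hz = 10, white_scale = 0.05),
    behavior = list(
      cross = list(hit_prob = 0.9523, rt_mean_s = 0.4626, rt_sd_s = 0.09,
                   stray_press_rate = 0.0302),
      bars = list(hit_prob = 0.969, rt_mean_s = 0.5013, rt_sd_s = 0.09,
                  nogo_press_prob = 0.0504)),
    preprocess = list(lo_hz = 0.1, hi_hz = 100, pre_s = 2, post_s = 62,
                      target_fs = 512, cycle_s = 0.5),
    analysis = list(f_oddball = 2, f_max_oddball = 20,
                    f_base = 10, f_max_base = 40,
                    z_crit_group = 3.1, z_thresh_individual = 1.64,
                    selection_roi = "LROI",
                    lroi = c("PO7", "P7", "P9", "PO9", "O1"),
                    rroi = c("PO8", "P8", "P10", "PO10", "O2"),
                    mo = c("Oz", "Iz", "O1", "O2"))
  )
  cfg <- .merge_config(defaults, list(...))
  .validate_config(cfg)
  structure(cfg, class = c("fpvs_config", "list"))
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  d <- cfg$design
  stopifnot(d$duration_s > 0, d$f_base > 0, d$oddball_every >= 2,
            cfg$acquisition$fs_hz > 0,
            cfg$preprocess$target_fs <= cfg$acquisition$fs_hz,
            cfg$analysis$z_crit_group > 0,
            cfg$analysis$z_thresh_individual > 0,
            cfg$n_participants >= 0)
  if ((d$duration_s * d$f_base) %% d$oddball_every != 0) {
    stop("config error: duration_s * f_base must be divisible by ",
         "oddball_every")
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' JSON (always available) or YAML (when the `yaml` package is installed),
#' merged over the defaults of [fpvs_config()].
#'
#' @param path config file.
#' @return a `fpvs_config`.
#' @export
read_config <- function(path) {
  over <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(fpvs_config, over)
}

.config_rois <- function(cfg) {
  list(LROI = fpvs_roi("LROI", cfg$analysis$lroi),
       RROI = fpvs_roi("RROI", cfg$analysis$rroi),
       MO = fpvs_roi("MO", cfg$analysis$mo))
}

#' Simulate key presses for a task-event schedule
#'
#' Behavioural generator paired with [plan_task_events()]: go events are
#' answered with probability `hit_prob` after a Gaussian reaction time
#' (clipped to the scoreable window), no-go events draw a press with
#' probability `nogo_press_prob`, and (cross task) stray presses occur at
#' rate `stray_press_rate` per event, placed outside response windows.
#'
#' @param events data.frame from [plan_task_events()].
#' @param task `"cross"` or `"bars"`.
#' @param beh behaviour parameter list, see `fpvs_config()$behavior`.
#' @param seed integer seed.
#' @return sorted numeric vector of press onsets (seconds).
#' @export
simulate_presses <- function(events, task, beh = fpvs_config()$behavior,
                             seed = 1L) {
  with_seed(seed, {
    presses <- numeric(0)
    p <- beh[[task]]
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$is_go) {
        if (runif(1) < p$hit_prob) {
          presses <- c(presses, e$onset_s +
                         max(0.16, min(0.99, rnorm(1, p$rt_mean_s,
                                                   p$rt_sd_s))))
        }
      } else if (!is.null(p$nogo_press_prob) &&
                 runif(1) < p$nogo_press_prob) {
        presses <- c(presses, e$onset_s +
                       max(0.16, rnorm(1, p$rt_mean_s - 0.044, p$rt_sd_s)))
      }
    }
    if (!is.null(p$stray_press_rate)) {
      n_stray <- rbinom(1, nrow(events), p$stray_press_rate)
      if (n_stray > 0) {
        # strays placed just before random events, outside response windows
        at <- sample(events$onset_s, n_stray, replace = TRUE) - runif(n_stray,
                                                                      0.2, 1)
        presses <- c(presses, pmax(0, at))
      }
    }
    sort(presses)
  })
}

#' Simulate a synthetic dataset on disk
#'
#' Plans one session per participant, synthesizes every sequence with the
#' configured responses and noise, simulates behavioural key presses, and
#' writes a fixture dataset: per sequence a little-endian float32 data
#' matrix (`*_data.bin`) plus a JSON sidecar (sampling rate, channels,
#' markers, events, presses and the injected ground truth), and a run
#' manifest with the full configuration and all derived seeds.
#'
#' @param config a `fpvs_config`.
#' @param out_dir output directory (created if needed).
#' @param montage montage data.frame.
#' @return the manifest, invisibly.
#' @export
fpvs_simulate <- function(config = fpvs_config(), out_dir,
                          montage = fpvs_montage()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_p <- config$n_participants
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, max(n_p, 1) * 3))
  oddball <- default_oddball_response(montage,
                                      amps = config$response$oddball_amps,
                                      rh_ratio = config$response$oddball_rh_ratio)
  base <- default_base_response(montage, amps = config$response$base_amps)
  noise <- do.call(noise_spec, config$noise)
  manifest <- list(config = unclass(config), participants = list())
  d <- config$design
  for (p in seq_len(n_p)) {
    pid <- sprintf("sub-%02d", p)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    stim <- demo_stimuli(d$n_words, d$n_letters, seed = seeds[3 * p - 2])
    session <- plan_session(stim, n_reps = d$n_reps,
                            task_order = d$task_order,
                            seed = seeds[3 * p - 1],
                            duration_s = d$duration_s, f_base = d$f_base,
                            oddball_every = d$oddball_every,
                            fade_in_s = d$fade_in_s,
                            fade_out_s = d$fade_out_s,
                            n_task_events = d$n_task_events)
    rec_seeds <- with_seed(seeds[3 * p],
                           sample.int(.Machine$integer.max,
                                      2 * length(session$sequences)))
    for (i in seq_along(session$sequences)) {
      plan <- session$sequences[[i]]
      rec <- synthesize_recording(plan, oddball, base, noise, montage,
                                  fs_hz = config$acquisition$fs_hz,
                                  pre_s = config$acquisition$pre_s,
                                  post_s = config$acquisition$post_s,
                                  seed = rec_seeds[2 * i - 1])
      presses <- simulate_presses(plan$events, plan$task, config$behavior,
                                   rec_seeds[2 * i])
      stem <- file.path(pdir, sprintf("seq-%02d", i))
      con <- file(paste0(stem, "_data.bin"), "wb")
      writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
      close(con)
      sidecar <- list(
        fs_hz = rec$fs_hz, n_channels = nrow(rec$data),
        n_samples = ncol(rec$data), channel_names = rec$channel_names,
        markers = rec$markers,
        task = plan$task, control_type = plan$control_type,
        discrimination = session$index$discrimination[i],
        rep = session$index$rep[i],
        duration_s = plan$duration_s, base_rate_hz = plan$base_rate_hz,
        oddball_hz = plan$oddball_hz,
        events = plan$events, presses = presses,
        truth = list(oddball_amps = oddball$amps,
                     oddball_freq = oddball$freq_hz,
                     base_amps = base$amps, base_freq = base$freq_hz,
                     oddball_topography = as.list(oddball$topography),
                     base_topography = as.list(base$topography),
                     noise = unclass(noise)))
      jsonlite::write_json(sidecar, paste0(stem, "_sidecar.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest$participants[[pid]] <- list(
      id = pid, n_sequences = length(session$sequences),
      index = session$index,
      stim_seed = seeds[3 * p - 2], session_seed = seeds[3 * p - 1],
      recording_seed = seeds[3 * p])
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read one fixture sequence back as a recording
#'
#' @param stem path stem, i.e. `<dir>/seq-01` for `seq-01_data.bin` +
#'   `seq-01_sidecar.json`.
#' @return a `fpvs_recording` (with `meta` fields from the sidecar).
#' @export
read_fixture_recording <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, "_sidecar.json"),
                              simplifyVector = TRUE)
  con <- file(paste0(stem, "_data.bin"), "rb")
  x <- readBin(con, "numeric", n = side$n_channels * side$n_samples,
               size = 4, endian = "little")
  close(con)
  side$presses <- as.numeric(unlist(side$presses))
  data <- matrix(x, nrow = side$n_channels,
                 dimnames = list(side$channel_names, NULL))
  structure(list(data = data, fs_hz = side$fs_hz,
                 channel_names = side$channel_names,
                 markers = side$markers,
                 plan = list(duration_s = side$duration_s,
                             task = side$task,
                             control_type = side$control_type,
                             base_rate_hz = side$base_rate_hz,
                             oddball_hz = side$oddball_hz),
                 sidecar = side),
            class = "fpvs_recording")
}

#' Analyse a simulated (or fixture) dataset
#'
#' Chains the full frequency-tagging analysis over a dataset written by
#' [fpvs_simulate()]: per participant and condition cell the repetitions
#' are preprocessed and averaged in the time domain, amplitude spectra are
#' extracted and ROI-averaged; harmonics are selected once per condition
#' on the grand-averaged selection-ROI spectrum; baseline-subtracted
#' amplitudes of the selected harmonics are summed per participant and
#' ROI; individual Z-scores are computed on non-corrected summed
#' amplitudes; behaviour is scored from events and presses.  Writes
#' `individual_results.tsv`, `group_summary.tsv`, `behavior.tsv` and
#' `run_manifest.json` into `out_dir`.
#'
#' @param config a `fpvs_config` (must match the simulated design).
#' @param data_dir dataset directory (with `manifest.json`).
#' @param out_dir output directory.
#' @param montage montage data.frame.
#' @return list with `individual`, `group`, `behavior` data.frames and
#'   `harmonics` (selected per condition), invisibly.
#' @export
fpvs_analyze <- function(config = fpvs_config(), data_dir, out_dir,
                         montage = fpvs_montage()) {
  mf_path <- file.path(data_dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("no manifest.json in ", data_dir, ": not a dataset directory")
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  participants <- names(manifest$participants)
  if (length(participants) == 0) stop("dataset contains no participants")
  rois <- .config_rois(config)
  pp <- config$preprocess
  an <- config$analysis

  spectra <- list()   # [[pid]][[cell]] -> list of per-ROI spectra
  behavior <- NULL
  for (pid in participants) {
    idx <- manifest$participants[[pid]]$index
    pdir <- file.path(data_dir, pid)
    cells <- unique(idx[, c("task", "discrimination", "control_type")])
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      rows <- which(idx$task == cell$task &
                      idx$discrimination == cell$discrimination &
                      idx$control_type == cell$control_type)
      epochs <- list()
      for (r in rows) {
        stem <- file.path(pdir, sprintf("seq-%02d", idx$sequence[r]))
        rec <- read_fixture_recording(stem)
        epochs[[length(epochs) + 1L]] <-
          preprocess(rec, pp$lo_hz, pp$hi_hz, pp$pre_s, pp$post_s,
                     pp$target_fs, montage = montage, cycle_s = pp$cycle_s)
        beh <- score_behavior(rec$sidecar$events, rec$sidecar$presses)
        behavior <- rbind(behavior, data.frame(
          participant = pid, sequence = idx$sequence[r],
          task = cell$task, discrimination = cell$discrimination,
          control_type = cell$control_type,
          n_go = beh$n_go, n_nogo = beh$n_nogo, hits = beh$hits,
          hit_rate = beh$hit_rate, fa_count = beh$fa_count,
          fa_rate = beh$fa_rate, mean_rt_s = beh$mean_rt_s,
          stringsAsFactors = FALSE))
      }
      spec <- amplitude_spectrum(average_epochs(epochs))
      key <- paste(cell$task, cell$discrimination, cell$control_type,
                   sep = "|")
      spectra[[pid]][[key]] <- lapply(rois, roi_average, spectrum = spec)
    }
  }

  # group-level harmonic selection per condition cell, on the selection ROI
  cells <- unique(do.call(rbind, lapply(participants, function(pid) {
    manifest$participants[[pid]]$index[, c("task", "discrimination",
                                           "control_type")]
  })))
  nyq <- pp$target_fs / 2
  cand_odd <- candidate_harmonics(an$f_oddball, an$f_base,
                                  min(an$f_max_oddball, nyq))
  cand_base <- candidate_harmonics(an$f_base, an$f_base,
                                   min(an$f_max_base, nyq),
                                   exclude_base = FALSE)
  harmonics <- list(); group <- NULL
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    key <- paste(cell$task, cell$discrimination, cell$control_type,
                 sep = "|")
    sel_spectra <- lapply(participants, function(pid) {
      spectra[[pid]][[key]][[an$selection_roi]]
    })
    gavg <- grand_average(sel_spectra)
    sel <- select_significant_harmonics(gavg, cand_odd,
                                        z_crit = an$z_crit_group)
    mo_spectra <- lapply(participants, function(pid) {
      spectra[[pid]][[key]][["MO"]]
    })
    gavg_mo <- grand_average(mo_spectra)
    sel_base <- select_significant_harmonics(gavg_mo, cand_base,
                                             z_crit = an$z_crit_group)
    harmonics[[key]] <- list(oddball = sel, base = sel_base)
    zz <- vapply(cand_odd, function(f) bin_stats(gavg, f)$z, 0)
    group <- rbind(group, data.frame(
      task = cell$task, discrimination = cell$discrimination,
      control_type = cell$control_type, roi = an$selection_roi,
      f_hz = cand_odd, group_z = zz,
      selected = cand_odd %in% sel, stringsAsFactors = FALSE))
  }

  individual <- NULL
  for (pid in participants) {
    for (key in names(spectra[[pid]])) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      sel <- harmonics[[key]]$oddball
      if (length(sel) == 0) sel <- cand_odd  # fall back: all candidates
      for (rn in names(rois)) {
        sp <- spectra[[pid]][[key]][[rn]]
        hs <- sum_harmonics(sp, sel)
        zrow <- summed_amplitude_z(sp, sel)
        individual <- rbind(individual, data.frame(
          participant = pid, task = parts[1], discrimination = parts[2],
          control_type = parts[3], roi = rn,
          n_harmonics = length(sel),
          summed_amp = zrow$summed_amp,
          summed_corrected_amp = hs$summed_corrected_amp,
          z = zrow$z, stringsAsFactors = FALSE))
      }
    }
  }
  sig <- individual_significance(individual, an$z_thresh_individual)
  individual <- sig$table

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(individual, "individual_results.tsv")
  wt(group, "group_summary.tsv")
  wt(behavior, "behavior.tsv")
  jsonlite::write_json(
    list(config = unclass(config), harmonics = harmonics,
         summary = sig$summary,
         rois = lapply(rois, function(r) r$channels)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(individual = individual, group = group,
                 behavior = behavior, harmonics = harmonics,
                 summary = sig$summary))
}
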