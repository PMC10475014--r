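#' Write a complete synthetic study to disk
#'
#' Runs the generator ([gen_cohort()], [gen_eeg()]) and writes the same
#' file layout the analysis pipeline reads: `melatonin.csv`,
#' `hypnograms.csv`, `probabilities.csv`, one EDF per participant-visit
#' under `eeg/`, the ground truth as `ground_truth.json`, and a
#' `study_config.json` describing the layout. Byte-identical output for
#' identical (config, seed).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param include_eeg Generate and write EDF signals (the bulky part);
#'   disable for melatonin/hypnogram-only studies.
#' @param include_sleep Generate hypnograms and stage probabilities;
#'   disable for melatonin-only (circadian phase) studies.
#' @return The study config path, invisibly.
#' @export
simulate_study <- function(config, dir, include_eeg = TRUE,
                           include_sleep = TRUE) {
  validate_sim_config(config)
  if (include_eeg && !include_sleep)
    stop("EEG synthesis requires hypnograms (include_sleep = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coh <- gen_cohort(config, include_sleep = include_sleep)

  mel <- list(); hyp <- list(); prob <- list()
  for (p in coh$participants) {
    for (v in p$visits) {
      for (day in c("baseline", "post")) {
        mel[[length(mel) + 1L]] <- data.frame(
          participant = p$id, visit = v$visit_index, condition = v$condition,
          day = day, series = I(list(
            if (day == "baseline") v$melatonin_baseline else v$melatonin_post)))
      }
      if (include_sleep) {
        hyp[[length(hyp) + 1L]] <- data.frame(
          participant = p$id, visit = v$visit_index, condition = v$condition,
          hypnogram = I(list(v$hypnogram)))
        prob[[length(prob) + 1L]] <- data.frame(
          participant = p$id, visit = v$visit_index, condition = v$condition,
          probabilities = I(list(v$probabilities)))
      }
    }
  }
  write_melatonin_csv(do.call(rbind, mel), file.path(dir, "melatonin.csv"))
  if (include_sleep) {
    write_hypnogram_csv(do.call(rbind, hyp), file.path(dir, "hypnograms.csv"))
    write_probability_csv(do.call(rbind, prob),
                          file.path(dir, "probabilities.csv"))
  }

  if (include_eeg) {
    dir.create(file.path(dir, "eeg"), showWarnings = FALSE)
    for (p in coh$participants) {
      for (v in p$visits) {
        sigs <- gen_eeg(v$hypnogram, config,
                        seed = derive_seed(config$seed, p$id, v$visit_index,
                                           purpose = 5L))
        write_edf(sigs, file.path(dir, "eeg", sprintf("p%02d_v%d_%s.edf",
                                                      p$id, v$visit_index,
                                                      v$condition)))
      }
    }
  }

  jsonlite::write_json(coh$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  cfg <- list(
    n_participants = config$n_participants,
    stimulus_onset = config$stimulus_onset,
    epoch_length = config$epoch_length,
    seed = config$seed,
    files = list(melatonin = "melatonin.csv",
                 hypnogram = if (include_sleep) "hypnograms.csv" else NULL,
                 probability = if (include_sleep) "probabilities.csv" else NULL,
                 eeg_dir = if (include_eeg) "eeg" else NULL)
  )
  path <- file.path(dir, "study_config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load all study inputs into memory
#'
#' Parses every file referenced by a study configuration, validating each
#' (monotone melatonin times, known stage labels, probability rows summing
#' to 1). EEG files are located but not loaded here (they are read lazily
#' per visit by [analyze_spectral()]).
#'
#' @param config A `study_config` (from [read_study_config()]) or the path
#'   to a study_config.json.
#' @return A list of class `study_data` with `config`, `melatonin`,
#'   `hypnograms`, `probabilities`, `eeg_files` (or NULL), `prc` (or
#'   NULL).
#' @export
read_inputs <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  mel <- read_melatonin_csv(config$files$melatonin)
  hyp <- if (!is.null(config$files$hypnogram)) {
    read_hypnogram_csv(config$files$hypnogram,
                       epoch_length = config$epoch_length)
  } else NULL
  prob <- if (!is.null(config$files$probability) &&
              file.exists(config$files$probability)) {
    read_probability_csv(config$files$probability)
  } else NULL
  eeg_files <- NULL
  if (!is.null(config$files$eeg_dir) && !is.null(hyp)) {
    eeg_files <- data.frame(
      participant = hyp$participant, visit = hyp$visit,
      condition = hyp$condition,
      path = file.path(config$files$eeg_dir,
                       sprintf("p%02d_v%d_%s.edf", hyp$participant,
                               hyp$visit, hyp$condition)))
    missing <- !file.exists(eeg_files$path)
    if (any(missing))
      stop("missing EDF file(s): ",
           paste(eeg_files$path[missing], collapse = ", "))
  }
  prc <- if (!is.null(config$files$prc)) read_prc_csv(config$files$prc)
  structure(
    list(config = config, melatonin = mel, hypnograms = hyp,
         probabilities = prob, eeg_files = eeg_files, prc = prc),
    class = "study_data"
  )
}

#' Estimate DLMOs and phase shifts for every participant-visit
#'
#' For each participant and condition: computes the participant-specific
#' threshold (2x mean of first three daytime samples) from the baseline-day
#' series, estimates both days' DLMOs, the phase change
#' `delta_phi = DLMO_baseline - DLMO_post` (negative = delay), the phase
#' angle `psi = stimulus_onset - DLMO_baseline`, the control-subtracted
#' `net_shift` (attached to flash rows), and, when a PRC is supplied, the
#' PRC-corrected shift at the cohort-mean flash phase angle.
#'
#' @param study A `study_data` from [read_inputs()].
#' @param prc Optional [phase_response_curve()] (defaults to the one in
#'   the study config, if any).
#' @param n_daytime Daytime samples for the threshold (default 3).
#' @param sustained Sustained-exceedance crossing rule (default TRUE).
#' @return Data.frame with one row per participant x condition.
#' @export
analyze_phase_shifts <- function(study, prc = NULL, n_daytime = 3,
                                 sustained = TRUE) {
  stopifnot(inherits(study, "study_data"))
  if (is.null(prc)) prc <- study$prc
  mel <- study$melatonin
  onset <- study$config$stimulus_onset
  keys <- unique(mel[, c("participant", "visit", "condition")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    pick <- function(day) {
      j <- which(mel$participant == keys$participant[i] &
                   mel$visit == keys$visit[i] & mel$day == day)
      if (length(j) != 1)
        stop("expected exactly one ", day, " series for participant ",
             keys$participant[i], " visit ", keys$visit[i])
      mel$series[[j]]
    }
    base <- pick("baseline")
    post <- pick("post")
    thr <- compute_threshold(base, n_daytime)
    d_base <- estimate_dlmo(base, thr, sustained)
    d_post <- estimate_dlmo(post, compute_threshold(post, n_daytime),
                            sustained)
    rows[[i]] <- data.frame(
      participant = keys$participant[i], visit = keys$visit[i],
      condition = keys$condition[i], threshold = thr,
      dlmo_baseline = d_base$onset_time, dlmo_post = d_post$onset_time,
      delta_phi = phase_shift(d_base, d_post),
      psi = suppressWarnings(phase_angle(d_base, onset)))
  }
  rec <- do.call(rbind, rows)
  rec$net_shift <- NA_real_
  for (p in unique(rec$participant)) {
    f <- rec$condition == "flash" & rec$participant == p
    c0 <- rec$condition == "placebo" & rec$participant == p
    if (any(f) && any(c0))
      rec$net_shift[f] <- net_shift(rec$delta_phi[f], rec$delta_phi[c0])
  }
  if (!is.null(prc)) {
    fl <- rec$condition == "flash"
    psi_mean <- mean(rec$psi[fl])
    rec$corrected_shift <- NA_real_
    rec$corrected_shift[fl] <- vapply(which(fl), function(i) {
      prc_correct(rec$delta_phi[i], rec$psi[i], psi_mean, prc)
    }, 0)
  }
  rec
}

#' Sleep-architecture metrics per participant, condition and window
#'
#' Stage durations (minutes), deep-to-light and sleep-to-wake transition
#' counts, and mean scored-stage probabilities, for each protocol analysis
#' window.
#'
#' @param study A `study_data` from [read_inputs()].
#' @param windows List of [analysis_window()]s (default: intervention and
#'   post).
#' @param taxonomy Deep-to-light taxonomy passed to [count_transitions()].
#' @return Tidy data.frame (participant, condition, window, metric,
#'   value); probability scores are NA when a stage is absent from a
#'   window.
#' @export
analyze_architecture <- function(study,
                                 windows = list(analysis_window("intervention"),
                                                analysis_window("post")),
                                 taxonomy = c("n3_to_light", "n2n3_to_n1")) {
  stopifnot(inherits(study, "study_data"))
  taxonomy <- match.arg(taxonomy)
  hyp <- study$hypnograms
  prob <- study$probabilities
  rows <- list()
  for (i in seq_len(nrow(hyp))) {
    h <- hyp$hypnogram[[i]]
    p <- NULL
    if (!is.null(prob)) {
      j <- which(prob$participant == hyp$participant[i] &
                   prob$visit == hyp$visit[i])
      if (length(j) == 1) p <- prob$probabilities[[j]]
    }
    for (w in windows) {
      hw <- slice_window(h, w)
      dur <- stage_durations(hw)
      vals <- c(
        setNames(as.list(dur), paste0("dur_", names(dur))),
        trans_deep_to_light = count_transitions(hw, "deep_to_light",
                                                taxonomy = taxonomy),
        trans_sleep_to_wake = count_transitions(hw, "sleep_to_wake"))
      if (!is.null(p)) {
        for (s in STAGES)
          vals[[paste0("pscore_", s)]] <- probability_score(p, h, s, w)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = hyp$participant[i], condition = hyp$condition[i],
        window = w$label, metric = names(vals),
        value = as.numeric(unlist(vals)), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Per-stage EEG band powers per participant, condition and window
#'
#' Reads each visit's EDF, preprocesses the central channels (resample to
#' 100 Hz, band-pass 0.2-49 Hz), and computes the per-stage Welch band
#' powers in each analysis window.
#'
#' @param study A `study_data` with EEG files.
#' @param windows List of [analysis_window()]s.
#' @param channels Channels to analyze (default C3, C4).
#' @return Tidy data.frame (participant, condition, window, channel,
#'   stage, band, power_uv2, n_epochs).
#' @export
analyze_spectral <- function(study,
                             windows = list(analysis_window("intervention"),
                                            analysis_window("post")),
                             channels = c("C3", "C4")) {
  stopifnot(inherits(study, "study_data"))
  if (is.null(study$eeg_files)) stop("study has no EEG files")
  hyp <- study$hypnograms
  rows <- list()
  for (i in seq_len(nrow(study$eeg_files))) {
    ef <- study$eeg_files[i, ]
    sigs <- read_edf(ef$path, channels = channels)
    sigs <- lapply(sigs, preprocess_psg)
    j <- which(hyp$participant == ef$participant & hyp$visit == ef$visit)
    h <- hyp$hypnogram[[j]]
    for (w in windows) {
      bp <- band_power_by_stage(sigs, h, w, channels = channels)
      if (nrow(bp) == 0) next
      bp$participant <- ef$participant
      bp$condition <- ef$condition
      rows[[length(rows) + 1L]] <- bp
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[, c("participant", "condition", "window", "channel", "stage",
          "band", "power_uv2", "n_epochs")]
}

#' Run the full analysis pipeline
#'
#' Orchestrates phase-shift estimation, sleep-architecture metrics,
#' spectral band powers and the study report, writing
#' `phase_records.csv`, `architecture.csv`, `band_power.csv`,
#' `report.json` and `provenance.json` to `out_dir`. Any stage failure
#' aborts and removes partial outputs. Deterministic given inputs.
#'
#' @param config Study config (path or `study_config`).
#' @param out_dir Output directory.
#' @param prc Optional [phase_response_curve()] or PRC CSV path.
#' @param transition_taxonomy Deep-to-light definition (see
#'   [count_transitions()]).
#' @param include_spectral Set FALSE to skip the EEG stage.
#' @return List with `phase_records`, `architecture`, `spectral`,
#'   `report`, invisibly.
#' @export
run_full_analysis <- function(config, out_dir, prc = NULL,
                              transition_taxonomy = "n3_to_light",
                              include_spectral = TRUE) {
  study <- read_inputs(config)
  if (is.character(prc)) prc <- read_prc_csv(prc)
  phase <- analyze_phase_shifts(study, prc = prc)
  arch <- if (!is.null(study$hypnograms)) {
    analyze_architecture(study, taxonomy = transition_taxonomy)
  } else NULL
  spec <- NULL
  if (include_spectral && !is.null(study$eeg_files))
    spec <- analyze_spectral(study)
  report <- summarize_cohort(phase, arch, spec)

  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wrote <- character()
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(wrote)
      if (created) unlink(out_dir, recursive = TRUE)
    }
  })
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (grepl("[.]csv$", name)) write.csv(obj, p, row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null")
    wrote <<- c(wrote, p)
  }
  wr(phase, "phase_records.csv")
  if (!is.null(arch)) wr(arch, "architecture.csv")
  if (!is.null(spec)) wr(spec, "band_power.csv")
  wr(unclass_report(report), "report.json")
  prov <- list(
    package_version = as.character(utils::packageVersion("flashsleep")),
    config_hash = fnv1a(jsonlite::toJSON(study$config, auto_unbox = TRUE,
                                         force = TRUE)),
    seed = study$config$seed,
    decisions = list(
      prc_correction = "multiplicative PRC(psi_mean)/PRC(psi_i)",
      transition_taxonomy = transition_taxonomy,
      dlmo_crossing = "sustained exceedance, linear interpolation"))
  wr(prov, "provenance.json")
  ok <- TRUE
  invisible(list(phase_records = phase, architecture = arch,
                 spectral = spec, report = report))
}

# study_report -> plain lists for JSON serialization
unclass_report <- function(r) {
  r <- unclass(r)
  if (!is.null(r$grubbs_phase_angle))
    r$grubbs_phase_angle <- unclass(r$grubbs_phase_angle)
  r$phase <- lapply(r$phase, function(x) {
    if (length(x) > 1) as.list(x) else as.numeric(x)
  })
  r
}
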