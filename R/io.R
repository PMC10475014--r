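# Plain-text study file formats.
#
# Melatonin CSV: participant, visit, condition, day, time_h,
#   concentration_pg_ml, is_daytime. (`day` distinguishes the baseline and
#   post-stimulus DLMO assessments within one lab visit.)
# Hypnogram CSV: participant, visit, condition, epoch_index, stage.
# Probability CSV: participant, visit, condition, epoch_index,
#   p_W, p_N1, p_N2, p_N3, p_REM.
# PRC CSV: phase_h_after_dlmo, shift_h.

#' Read a phase response curve from CSV
#'
#' Expects columns `phase_h_after_dlmo` and `shift_h`. The package ships a
#' small linear synthetic PRC for testing
#' (`system.file("extdata", "prc_linear_synthetic.csv", package =
#' "flashsleep")`); it is *not* a physiological curve — supply a published
#' PRC table for real analyses.
#'
#' @param path CSV path.
#' @return A [phase_response_curve()].
#' @export
read_prc_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase_h_after_dlmo", "shift_h")
  if (!all(need %in% names(df)))
    stop("PRC CSV must have columns: ", paste(need, collapse = ", "))
  phase_response_curve(df$phase_h_after_dlmo, df$shift_h)
}

#' Read a melatonin CSV into per-assessment series
#'
#' Validates monotone times and nonnegative concentrations per
#' participant-visit-day group, reporting the offending file and row on
#' failure.
#'
#' @param path CSV path (see format note in this file's docs).
#' @return A data.frame with one row per (participant, visit, condition,
#'   day) and a list-column `series` of [melatonin_series()] objects.
#' @export
read_melatonin_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "visit", "condition", "day", "time_h",
            "concentration_pg_ml", "is_daytime")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  keys <- unique(df[, c("participant", "visit", "condition", "day")])
  keys <- keys[order(keys$participant, keys$visit, keys$day), ]
  series <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- df$participant == keys$participant[i] &
      df$visit == keys$visit[i] & df$day == keys$day[i]
    sub <- df[sel, ]
    sub <- sub[order(sub$time_h), ]
    if (any(duplicated(sub$time_h))) {
      row <- which(sel)[which(duplicated(sub$time_h))[1]]
      stop(path, " row ", row, ": non-monotone (duplicated) time for ",
           "participant ", keys$participant[i])
    }
    series[[i]] <- melatonin_series(sub$time_h, sub$concentration_pg_ml,
                                    as.logical(sub$is_daytime))
  }
  keys$series <- series
  keys
}

write_melatonin_csv <- function(rows, path) {
  # rows: data.frame with list-column series, as from read_melatonin_csv
  out <- list()
  for (i in seq_len(nrow(rows))) {
    s <- rows$series[[i]]
    out[[i]] <- data.frame(
      participant = rows$participant[i], visit = rows$visit[i],
      condition = rows$condition[i], day = rows$day[i],
      time_h = s$times, concentration_pg_ml = s$concentrations,
      is_daytime = s$daytime_flags)
  }
  write.csv(do.call(rbind, out), path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' @param path CSV with columns participant, visit, condition,
#'   epoch_index, stage. Unknown stage labels are an error naming the row.
#' @param epoch_length Epoch length in seconds (default 15).
#' @return Data.frame keyed by (participant, visit, condition) with a
#'   list-column `hypnogram`.
#' @export
read_hypnogram_csv <- function(path, epoch_length = 15) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "visit", "condition", "epoch_index", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$stage %in% STAGE_LEVELS)
  if (length(bad) > 0)
    stop(path, " row ", bad[1], ": unknown stage label \"",
         df$stage[bad[1]], "\"")
  keys <- unique(df[, c("participant", "visit", "condition")])
  keys <- keys[order(keys$participant, keys$visit), ]
  hyp <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$participant == keys$participant[i] &
                df$visit == keys$visit[i], ]
    sub <- sub[order(sub$epoch_index), ]
    hyp[[i]] <- hypnogram(sub$stage, epoch_length = epoch_length,
                          start_time = 0)
  }
  keys$hypnogram <- hyp
  keys
}

write_hypnogram_csv <- function(rows, path) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    h <- rows$hypnogram[[i]]
    out[[i]] <- data.frame(
      participant = rows$participant[i], visit = rows$visit[i],
      condition = rows$condition[i],
      epoch_index = seq_along(h$stages), stage = h$stages)
  }
  write.csv(do.call(rbind, out), path, row.names = FALSE)
  invisible(path)
}

#' Read a stage-probability CSV
#'
#' @param path CSV with columns participant, visit, condition,
#'   epoch_index, p_W, p_N1, p_N2, p_N3, p_REM.
#' @return Data.frame keyed by (participant, visit, condition) with a
#'   list-column `probabilities` of [stage_probabilities()] matrices.
#' @export
read_probability_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pcols <- paste0("p_", STAGES)
  need <- c("participant", "visit", "condition", "epoch_index", pcols)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  keys <- unique(df[, c("participant", "visit", "condition")])
  keys <- keys[order(keys$participant, keys$visit), ]
  probs <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$participant == keys$participant[i] &
                df$visit == keys$visit[i], ]
    sub <- sub[order(sub$epoch_index), ]
    m <- as.matrix(sub[, pcols])
    colnames(m) <- STAGES
    probs[[i]] <- stage_probabilities(m)
  }
  keys$probabilities <- probs
  keys
}

write_probability_csv <- function(rows, path) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    p <- rows$probabilities[[i]]
    d <- data.frame(participant = rows$participant[i],
                    visit = rows$visit[i],
                    condition = rows$condition[i],
                    epoch_index = seq_len(nrow(p)))
    d[paste0("p_", STAGES)] <- as.data.frame(unclass(p))
    out[[i]] <- d
  }
  write.csv(do.call(rbind, out), path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration JSON
#'
#' @param path JSON file with fields `n_participants`, `stimulus_onset`,
#'   `epoch_length`, `seed`, `files` (melatonin/hypnogram/probability
#'   paths, `eeg_dir`, optional `prc`), and optional `windows` overrides.
#'   Relative paths resolve against the JSON file's directory.
#' @return A list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  need <- c("n_participants", "files")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop(path, ": missing config field(s): ", paste(miss, collapse = ", "))
  cfg$base_dir <- base
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  for (f in c("melatonin", "hypnogram", "probability", "prc", "eeg_dir")) {
    if (!is.null(cfg$files[[f]])) cfg$files[[f]] <- resolve(cfg$files[[f]])
  }
  if (is.null(cfg$stimulus_onset)) cfg$stimulus_onset <- 0.5
  if (is.null(cfg$epoch_length)) cfg$epoch_length <- 15
  if (is.null(cfg$seed)) cfg$seed <- 0L
  class(cfg) <- "study_config"
  cfg
}

# Tiny deterministic content hash for provenance records (no digest
# package in this environment): a 31-bit polynomial rolling hash.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
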