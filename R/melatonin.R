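#' Construct a salivary melatonin series
#'
#' A melatonin series holds timestamped salivary melatonin concentrations
#' for one participant-visit-day, on a continuous time axis in hours
#' relative to habitual sleep onset (HSOn). Daytime flags mark the samples
#' that define the participant-specific DLMO threshold.
#'
#' @param times Numeric vector, hours relative to HSOn, strictly increasing.
#' @param concentrations Numeric vector of melatonin levels, pg/mL, >= 0.
#' @param daytime_flags Logical vector; TRUE for daytime baseline samples.
#' @return An object of class `melatonin_series`.
#' @export
#' @examples
#' s <- melatonin_series(c(-8, -7.5, -7, -3, -2.5),
#'                       c(1.2, 0.9, 1.1, 4.0, 11.0),
#'                       c(TRUE, TRUE, TRUE, FALSE, FALSE))
melatonin_series <- function(times, concentrations, daytime_flags) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  daytime_flags <- as.logical(daytime_flags)
  if (length(times) != length(concentrations) ||
      length(times) != length(daytime_flags))
    stop("times, concentrations and daytime_flags must have equal length")
  if (length(times) < 2) stop("need at least two samples")
  if (any(!is.finite(times)) || any(!is.finite(concentrations)))
    stop("times and concentrations must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  structure(
    list(times = times, concentrations = concentrations,
         daytime_flags = daytime_flags),
    class = "melatonin_series"
  )
}

#' @export
print.melatonin_series <- function(x, ...) {
  cat(sprintf("<melatonin_series> %d samples, %.2f to %.2f h rel. HSOn, %d daytime\n",
              length(x$times), min(x$times), max(x$times),
              sum(x$daytime_flags)))
  invisible(x)
}

#' Participant-specific DLMO threshold
#'
#' The threshold is twice the mean of the first `n_daytime` daytime
#' melatonin concentrations (in time order).
#'
#' @param series A [melatonin_series()].
#' @param n_daytime Number of daytime samples to average (default 3).
#' @return Threshold in pg/mL.
#' @export
#' @examples
#' s <- melatonin_series(c(-8, -7.5, -7, -2), c(1, 2, 3, 10),
#'                       c(TRUE, TRUE, TRUE, FALSE))
#' compute_threshold(s)  # 2 * mean(1, 2, 3) = 4
compute_threshold <- function(series, n_daytime = 3) {
  stopifnot(inherits(series, "melatonin_series"))
  idx <- which(series$daytime_flags)
  if (length(idx) < n_daytime)
    stop("insufficient daytime baseline: need ", n_daytime,
         " daytime samples, have ", length(idx))
  2 * mean(series$concentrations[idx[seq_len(n_daytime)]])
}

#' Estimate dim light melatonin onset (DLMO)
#'
#' DLMO is the time at which the melatonin concentration first exceeds the
#' participant-specific threshold. By default "exceeds" requires a
#' sustained exceedance: the first run of consecutive samples at or above
#' threshold that is either at least two samples long or reaches the end of
#' the series (a trailing single sample cannot be refuted). The onset time
#' is linearly interpolated between the last sample below threshold and the
#' first sample of that run; a sample landing exactly on the threshold is
#' taken as the onset time itself.
#'
#' @param series A [melatonin_series()].
#' @param threshold Threshold in pg/mL (> 0), e.g. from
#'   [compute_threshold()].
#' @param sustained If TRUE (default), require sustained exceedance; if
#'   FALSE, the plain first crossing is used.
#' @return An object of class `dlmo_estimate` with fields `onset_time`
#'   (hours rel. HSOn), `threshold`, and `crossing_indices` (the bracketing
#'   sample pair).
#' @export
#' @examples
#' s <- melatonin_series(c(-4, -3.5, -3), c(1.0, 1.8, 3.0),
#'                       c(FALSE, FALSE, FALSE))
#' estimate_dlmo(s, 2.0)$onset_time  # -3.5 + 0.5*(2-1.8)/(3-1.8)
estimate_dlmo <- function(series, threshold, sustained = TRUE) {
  stopifnot(inherits(series, "melatonin_series"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  conc <- series$concentrations
  times <- series$times
  n <- length(conc)
  above <- conc >= threshold
  if (!any(above)) stop("no onset detected: series never reaches threshold")
  # runs of consecutive exceedance
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (sustained) {
    ok <- r$lengths[cand] >= 2L | ends[cand] == n
    cand <- cand[ok]
    if (length(cand) == 0)
      stop("no onset detected: no sustained exceedance of threshold")
  }
  i <- starts[cand[1L]]
  if (i == 1L)
    stop("rise not captured: series begins at or above threshold")
  onset <- if (conc[i] == threshold) {
    times[i]
  } else {
    frac <- (threshold - conc[i - 1L]) / (conc[i] - conc[i - 1L])
    times[i - 1L] + frac * (times[i] - times[i - 1L])
  }
  structure(
    list(onset_time = onset, threshold = threshold,
         crossing_indices = c(i - 1L, i)),
    class = "dlmo_estimate"
  )
}

#' @export
print.dlmo_estimate <- function(x, ...) {
  cat(sprintf("<dlmo_estimate> onset %.3f h rel. HSOn (threshold %.3g pg/mL)\n",
              x$onset_time, x$threshold))
  invisible(x)
}
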