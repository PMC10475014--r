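#' Construct a hypnogram
#'
#' A hypnogram is a sequence of scored sleep stages in fixed-length epochs
#' (15 s by default). Stages are W, N1, N2, N3, REM; ARTIFACT marks epochs
#' excluded from all metrics.
#'
#' @param stages Character vector over W, N1, N2, N3, REM, ARTIFACT.
#' @param epoch_length Epoch length in seconds (default 15).
#' @param start_time Start of the first epoch, hours relative to HSOn.
#' @return An object of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N2", "N3"))
#' stage_durations(h)
hypnogram <- function(stages, epoch_length = 15, start_time = 0) {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("hypnogram must be nonempty")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad) > 0)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (epoch_length <= 0) stop("epoch_length must be > 0")
  structure(
    list(stages = stages, epoch_length = epoch_length,
         start_time = start_time),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %gs from %.2f h rel. HSOn (%.2f h total)\n",
              length(x$stages), x$epoch_length, x$start_time,
              length(x$stages) * x$epoch_length / 3600))
  invisible(x)
}

# Epoch start times in hours rel. HSOn.
epoch_starts <- function(h) {
  h$start_time + (seq_along(h$stages) - 1L) * h$epoch_length / 3600
}

#' Protocol analysis windows
#'
#' The intervention window spans the hour of light (or sham) exposure,
#' [+0.5 h, +1.5 h] after HSOn (flashes start 30 min after HSOn and last
#' 1 h); the post window spans the following 6.5 h, [+1.5 h, +8.0 h].
#'
#' @param label One of "intervention", "post", or "custom".
#' @param start,end Window bounds in hours rel. HSOn (required for
#'   "custom"; defaults supplied for the protocol windows).
#' @return A list of class `analysis_window` with `label`, `start`, `end`.
#' @export
#' @examples
#' analysis_window("intervention")
analysis_window <- function(label = c("intervention", "post", "custom"),
                            start = NULL, end = NULL) {
  label <- match.arg(label)
  if (label == "intervention") {
    start <- if (is.null(start)) 0.5 else start
    end <- if (is.null(end)) 1.5 else end
  } else if (label == "post") {
    start <- if (is.null(start)) 1.5 else start
    end <- if (is.null(end)) 8.0 else end
  } else if (is.null(start) || is.null(end)) {
    stop("custom window requires start and end")
  }
  if (end <= start) stop("window end must exceed start")
  structure(list(label = label, start = start, end = end),
            class = "analysis_window")
}

#' Slice a hypnogram to an analysis window
#'
#' Keeps epochs whose start time lies in `[start, end)`; boundary epochs are
#' assigned by their start time (half-open windows), which makes durations
#' additive across adjacent windows.
#'
#' @param h A [hypnogram()].
#' @param window An [analysis_window()].
#' @return A new, shorter [hypnogram()].
#' @export
slice_window <- function(h, window) {
  stopifnot(inherits(h, "hypnogram"), inherits(window, "analysis_window"))
  st <- epoch_starts(h)
  keep <- st >= window$start & st < window$end
  if (!any(keep))
    stop(sprintf("window [%g, %g) does not overlap hypnogram span [%g, %g)",
                 window$start, window$end, min(st),
                 max(st) + h$epoch_length / 3600))
  hypnogram(h$stages[keep], h$epoch_length, st[which(keep)[1L]])
}

#' Minutes spent in each sleep stage
#'
#' Duration per stage is the epoch count times the epoch length. ARTIFACT
#' epochs are excluded; the non-artifact durations always sum to the
#' non-artifact epoch count times the epoch length.
#'
#' @param h A [hypnogram()].
#' @return Named numeric vector of minutes for W, N1, N2, N3, REM.
#' @export
#' @examples
#' stage_durations(hypnogram(rep("N2", 240)))  # 60 min of N2
stage_durations <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  st <- h$stages[h$stages != "ARTIFACT"]
  if (length(st) == 0) stop("all epochs are ARTIFACT; no durations defined")
  counts <- table(factor(st, levels = STAGES))
  setNames(as.numeric(counts) * h$epoch_length / 60, STAGES)
}

#' Count stage transitions of a given kind
#'
#' Scans adjacent epoch pairs (a, b). With `kind = "deep_to_light"` the
#' default taxonomy counts pairs with a = N3 and b in N2 or N1; the
#' alternative `taxonomy = "n2n3_to_n1"` counts a in N2 or N3 and b = N1
#' (two published phrasings of sleep-lightening transitions).
#' `kind = "sleep_to_wake"` counts a in N1, N2, N3, REM and b = W.
#' ARTIFACT epochs break adjacency: no pair involving or spanning an
#' artifact epoch is counted.
#'
#' @param h A [hypnogram()].
#' @param kind "deep_to_light" or "sleep_to_wake".
#' @param taxonomy For deep-to-light only: "n3_to_light" (default) or
#'   "n2n3_to_n1".
#' @return Integer count.
#' @export
#' @examples
#' h <- hypnogram(c("N2", "N3", "N3", "N1", "W", "N1", "N2"))
#' count_transitions(h, "deep_to_light")  # 1
#' count_transitions(h, "sleep_to_wake")  # 1
count_transitions <- function(h, kind = c("deep_to_light", "sleep_to_wake"),
                              taxonomy = c("n3_to_light", "n2n3_to_n1")) {
  stopifnot(inherits(h, "hypnogram"))
  kind <- match.arg(kind)
  taxonomy <- match.arg(taxonomy)
  s <- h$stages
  if (length(s) < 2) return(0L)
  a <- s[-length(s)]
  b <- s[-1L]
  valid <- a != "ARTIFACT" & b != "ARTIFACT"
  hit <- switch(kind,
    deep_to_light = if (taxonomy == "n3_to_light") {
      a == "N3" & b %in% c("N2", "N1")
    } else {
      a %in% c("N2", "N3") & b == "N1"
    },
    sleep_to_wake = a %in% c("N1", "N2", "N3", "REM") & b == "W"
  )
  sum(hit & valid)
}

#' Construct per-epoch stage probabilities
#'
#' Probability scoring from an automatic sleep stager: each epoch carries a
#' probability vector over W, N1, N2, N3, REM that must sum to 1 (within
#' 1e-6).
#'
#' @param p Numeric matrix, one row per epoch, five columns (W, N1, N2,
#'   N3, REM order; named columns are reordered).
#' @return An object of class `stage_probabilities` (the validated matrix).
#' @export
stage_probabilities <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 5) stop("need five probability columns (W, N1, N2, N3, REM)")
  if (!is.null(colnames(p))) {
    if (!setequal(colnames(p), STAGES)) stop("columns must be W, N1, N2, N3, REM")
    p <- p[, STAGES, drop = FALSE]
  } else {
    colnames(p) <- STAGES
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("each epoch's probabilities must sum to 1 (within 1e-6)")
  structure(p, class = c("stage_probabilities", "matrix", "array"))
}

#' Mean scored-stage probability within a window
#'
#' For a given stage, averages the scorer's probability of that stage over
#' the window's epochs that were *scored* as that stage (e.g., mean p(W)
#' over epochs scored W). Returns NA, not 0, when the stage does not occur
#' in the window — stages absent during a 1-h intervention window are
#' simply missing, mirroring reduced degrees of freedom in downstream
#' models. ARTIFACT epochs are excluded.
#'
#' @param probs A [stage_probabilities()] aligned to `h` (same epoch
#'   count).
#' @param h A [hypnogram()].
#' @param stage One of W, N1, N2, N3, REM.
#' @param window Optional [analysis_window()]; defaults to the full record.
#' @return Mean probability in [0, 1], or NA if the stage is absent.
#' @export
#' @examples
#' h <- hypnogram(c("W", "W"))
#' p <- stage_probabilities(rbind(c(0.89, 0.04, 0.02, 0.00, 0.05),
#'                                c(0.64, 0.19, 0.03, 0.00, 0.14)))
#' probability_score(p, h, "W")  # 0.765
probability_score <- function(probs, h, stage, window = NULL) {
  stopifnot(inherits(probs, "stage_probabilities"), inherits(h, "hypnogram"))
  stage <- match.arg(stage, STAGES)
  if (nrow(probs) != length(h$stages))
    stop("probability matrix and hypnogram lengths differ (",
         nrow(probs), " vs ", length(h$stages), ")")
  keep <- rep(TRUE, length(h$stages))
  if (!is.null(window)) {
    st <- epoch_starts(h)
    keep <- st >= window$start & st < window$end
  }
  sel <- keep & h$stages == stage
  if (!any(sel)) return(NA_real_)
  mean(probs[sel, stage])
}
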