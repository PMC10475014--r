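# Minimal European Data Format (EDF) I/O.
#
# No EDF reader is available in this R environment, so the subset of the
# format the pipeline needs is implemented here: continuous 16-bit signals,
# one-second data records, equal record counts per signal. Physical scaling
# follows the EDF linear digital->physical map. Annotations, EDF+ and
# discontinuous files are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write PSG signals to an EDF file
#'
#' Writes a named list of equal-rate [psg_signal()]s as a continuous EDF
#' recording with 1-s data records. Samples are clipped to
#' `[-phys_lim, phys_lim]` microvolts and quantized to 16 bits; trailing
#' samples that do not fill a whole second are dropped. The signal start
#' time (hours rel. HSOn) is stored in the recording-identification field
#' and recovered by [read_edf()].
#'
#' @param signals Named list of [psg_signal()]s with identical `fs`,
#'   length and `start_time`; `fs` must be an integer.
#' @param path Output file path.
#' @param phys_lim Physical range half-width in microvolts (default 400).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, phys_lim = 400) {
  if (length(signals) == 0) stop("no signals to write")
  fs <- signals[[1]]$fs
  n <- length(signals[[1]]$samples)
  st <- signals[[1]]$start_time
  for (s in signals) {
    stopifnot(inherits(s, "psg_signal"))
    if (s$fs != fs || length(s$samples) != n || s$start_time != st)
      stop("all signals must share fs, length and start_time")
  }
  if (abs(fs - round(fs)) > 1e-9) stop("fs must be an integer for EDF records")
  fs <- as.integer(round(fs))
  ns <- length(signals)
  nrec <- n %/% fs
  if (nrec < 1) stop("signals shorter than one EDF record (1 s)")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(sprintf("Startdate 01-JAN-2022 rel_hson=%.6f", st), 80),
    edf_pad("01.01.22", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  labels <- vapply(signals, function(s) paste("EEG", s$channel), "")
  field(labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep(sprintf("%g", -phys_lim), ns), 8)  # physical minimum
  field(rep(sprintf("%g", phys_lim), ns), 8)   # physical maximum
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("BP:0.2-49Hz", ns), 80)            # prefiltering (free text)
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)

  # digital conversion: phys = a * dig + b with a = 2*lim/65535
  a <- (2 * phys_lim) / 65535
  b <- phys_lim - a * 32767
  dig <- lapply(signals, function(s) {
    x <- pmin(pmax(s$samples[seq_len(nrec * fs)], -phys_lim), phys_lim)
    as.integer(round((x - b) / a))
  })
  # interleave per record
  out <- matrix(0L, nrow = fs * ns, ncol = nrec)
  for (j in seq_len(ns)) {
    out[(j - 1L) * fs + seq_len(fs), ] <- matrix(dig[[j]], fs, nrec)
  }
  writeBin(as.vector(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous EDF file written by [write_edf()] (or any plain EDF
#' with equal-duration records), applying the linear digital-to-physical
#' scaling per signal. Channel labels have an "EEG " prefix stripped and
#' are matched case-insensitively downstream.
#'
#' @param path EDF file path.
#' @param channels Optional character vector restricting which channels to
#'   return (case-insensitive); an absent requested channel is an error.
#' @return Named list of [psg_signal()]s.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  rd(80)                      # patient
  recfield <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8))
  dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  start_time <- 0
  m <- regmatches(recfield, regexec("rel_hson=(-?[0-9.]+)", recfield))[[1]]
  if (length(m) == 2) start_time <- as.numeric(m[2])

  total <- sum(spr) * nrec
  raw <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
  labels <- sub("^EEG +", "", labels)
  sel <- seq_len(ns)
  if (!is.null(channels)) {
    sel <- match(tolower(channels), tolower(labels))
    if (anyNA(sel))
      stop("channel(s) absent from EDF: ",
           paste(channels[is.na(sel)], collapse = ", "))
  }
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  out <- list()
  for (j in sel) {
    idx <- as.vector(outer(offs[j] + seq_len(spr[j]),
                           (seq_len(nrec) - 1L) * per_rec, `+`))
    a <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    b <- pmin_[j] - a * dmin_[j]
    out[[labels[j]]] <- psg_signal(labels[j], spr[j] / recdur,
                                   a * raw[idx] + b, start_time)
  }
  out
}
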