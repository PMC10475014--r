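# Independent brute-force oracles used across tests. These deliberately use
# plain loops and direct formula transcription, not the package's code paths.

# DLMO by scanning all adjacent sample pairs: find the first pair (i, i+1)
# bracketing the threshold such that the exceedance at i+1 is sustained
# (sample i+2 also >= threshold, or i+1 is the last sample), then linearly
# interpolate. Returns NA if no such crossing.
oracle_dlmo <- function(times, conc, threshold, sustained = TRUE) {
  n <- length(conc)
  if (conc[1] >= threshold) {
    # rise not captured if the series *starts* in a sustained exceedance;
    # a single unsustained opening spike is skipped like any other spike
    if (!sustained || n == 1 || conc[2] >= threshold) return(NA_real_)
  }
  for (i in seq_len(n - 1)) {
    if (conc[i] < threshold && conc[i + 1] >= threshold) {
      ok <- TRUE
      if (sustained) {
        # the run starting at i+1 must extend to a 2nd sample or hit the end
        if (i + 2 <= n && conc[i + 2] < threshold) ok <- FALSE
      }
      if (ok) {
        if (conc[i + 1] == threshold) return(times[i + 1])
        frac <- (threshold - conc[i]) / (conc[i + 1] - conc[i])
        return(times[i] + frac * (times[i + 1] - times[i]))
      }
    }
  }
  NA_real_
}

# Transition counting by explicit pairwise loop.
oracle_transitions <- function(stages, kind, taxonomy = "n3_to_light") {
  count <- 0L
  for (i in seq_len(length(stages) - 1)) {
    a <- stages[i]; b <- stages[i + 1]
    if (a == "ARTIFACT" || b == "ARTIFACT") next
    hit <- if (kind == "deep_to_light") {
      if (taxonomy == "n3_to_light") {
        a == "N3" && b %in% c("N2", "N1")
      } else {
        a %in% c("N2", "N3") && b == "N1"
      }
    } else {
      a %in% c("N1", "N2", "N3", "REM") && b == "W"
    }
    if (hit) count <- count + 1L
  }
  count
}

# Grubbs statistic and critical value transcribed directly from the
# published closed form.
oracle_grubbs <- function(x, alpha) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(G = G, crit = crit, outlier = G > crit)
}

# Random melatonin-like series: baseline hum plus a ramp, with jitter.
random_series <- function() {
  n <- sample(8:24, 1)
  times <- sort(runif(n, -8, 2))
  while (any(diff(times) <= 0)) times <- sort(runif(n, -8, 2))
  conc <- abs(1 + cumsum(rnorm(n, 0.4, 0.8)))
  list(times = times, conc = conc)
}

random_hypnogram <- function(n = NULL, p_artifact = 0.05) {
  if (is.null(n)) n <- sample(5:200, 1)
  stages <- sample(c("W", "N1", "N2", "N3", "REM", "ARTIFACT"), n,
                   replace = TRUE,
                   prob = c(0.1, 0.15, 0.3, 0.25, 0.15, p_artifact))
  hypnogram(stages)
}
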