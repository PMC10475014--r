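#' Simulate a hypnogram as a first-order Markov chain
#'
#' Draws a stage sequence over W, N1, N2, N3, REM at fixed epoch steps from
#' the config's transition matrix, starting (by default) in N1 at sleep
#' onset. Epoch count is `floor(duration * 3600 / epoch_length)`.
#'
#' @param config A [sim_config()] (supplies the transition matrix and epoch
#'   length).
#' @param duration Recording length in hours (> 0).
#' @param seed Integer seed for this chain.
#' @param start_stage Initial stage (default "N1").
#' @return A [hypnogram()] starting at time 0 (HSOn).
#' @export
#' @examples
#' h <- gen_hypnogram(sim_config(seed = 1), duration = 1, seed = 5)
#' length(h$stages)  # 240 epochs
gen_hypnogram <- function(config, duration, seed, start_stage = "N1") {
  validate_sim_config(config)
  if (duration <= 0) stop("duration must be > 0")
  start_stage <- match.arg(start_stage, STAGES)
  tm <- config$hypnogram_transition_matrix
  # reject degenerate matrices: a state with no outgoing mass would absorb
  if (any(rowSums(tm) == 0)) stop("degenerate transition matrix")
  n_epochs <- floor(duration * 3600 / config$epoch_length)
  if (n_epochs < 1) stop("duration shorter than one epoch")
  cum <- t(apply(tm, 1, cumsum))
  set.seed(seed)
  u <- runif(n_epochs)
  idx <- integer(n_epochs)
  cur <- match(start_stage, STAGES)
  for (e in seq_len(n_epochs)) {
    cur <- findInterval(u[e], cum[cur, ], left.open = TRUE) + 1L
    idx[e] <- cur
  }
  hypnogram(STAGES[idx], epoch_length = config$epoch_length, start_time = 0)
}

#' Default scorer confusion matrix
#'
#' Row s gives the expected probability vector emitted by an automatic
#' scorer for an epoch whose true stage is s. The default emulates a
#' high-fidelity template-matching scorer: ~0.9 mass on the scored stage,
#' spread over plausible confusions (W with N1/REM, N2 with N1/N3).
#'
#' @return 5x5 row-stochastic matrix with dimnames over W, N1, N2, N3, REM.
#' @export
default_confusion_matrix <- function() {
  m <- matrix(c(
    # W     N1    N2    N3    REM
    0.89, 0.04, 0.02, 0.00, 0.05,  # true W
    0.05, 0.85, 0.06, 0.00, 0.04,  # true N1
    0.01, 0.04, 0.89, 0.05, 0.01,  # true N2
    0.00, 0.01, 0.08, 0.91, 0.00,  # true N3
    0.03, 0.05, 0.02, 0.00, 0.90   # true REM
  ), nrow = 5, byrow = TRUE, dimnames = list(STAGES, STAGES))
  m
}

#' Simulate per-epoch stage-probability vectors
#'
#' For each epoch, draws a probability vector from a Dirichlet distribution
#' centered on the confusion-matrix row of the scored stage
#' (`Dirichlet(concentration * confusion[stage, ])`). Zero confusion
#' entries stay exactly zero, so an identity confusion matrix yields
#' one-hot vectors; every vector sums to 1 by construction.
#'
#' @param h A [hypnogram()].
#' @param confusion 5x5 matrix, rows summing to 1, entries nonnegative.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration; larger values concentrate
#'   vectors around the confusion row (default 50 keeps the argmax on the
#'   scored stage with high probability for diagonally dominant rows).
#' @return A [stage_probabilities()] matrix aligned to `h`.
#' @export
gen_stage_probabilities <- function(h, confusion = default_confusion_matrix(),
                                    seed = 1L, concentration = 50) {
  stopifnot(inherits(h, "hypnogram"))
  confusion <- as.matrix(confusion)
  if (!identical(dim(confusion), c(5L, 5L)))
    stop("confusion must be a 5x5 matrix")
  if (any(confusion < 0)) stop("confusion entries must be nonnegative")
  if (any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion rows must sum to 1")
  if (is.null(rownames(confusion))) dimnames(confusion) <- list(STAGES, STAGES)
  if (any(h$stages == "ARTIFACT"))
    stop("cannot generate probabilities for ARTIFACT epochs")
  set.seed(seed)
  n <- length(h$stages)
  p <- matrix(0, n, 5, dimnames = list(NULL, STAGES))
  for (s in STAGES) {
    rows <- which(h$stages == s)
    if (length(rows) == 0) next
    alpha <- concentration * confusion[s, ]
    pos <- alpha > 0
    if (sum(pos) == 1) {
      p[rows, pos] <- 1
      next
    }
    g <- matrix(0, length(rows), 5)
    for (j in which(pos)) g[, j] <- rgamma(length(rows), shape = alpha[j])
    p[rows, ] <- g / rowSums(g)
  }
  stage_probabilities(p)
}
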