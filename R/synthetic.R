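#' @include dynamics.R preprocess.R
NULL

#' Generate a noisy spiral validation dataset
#'
#' Simulates sequences of a planar linear system with complex eigenvalues
#' (an inward spiral) from random initial conditions via the closed-form
#' flow, then adds Gaussian observation noise. The noiseless states are
#' retained as ground truth, so estimator output can be scored directly
#' against the true state at any timepoint. Alongside the true drift
#' matrix, perturbed candidate matrices of increasing magnitude are
#' emitted for system-identification experiments.
#'
#' @param nSequences number of observation sequences.
#' @param nTimepoints observations per sequence (>= 2).
#' @param A true 2x2 drift matrix (must spiral inward, else a warning).
#' @param noiseSd observation noise standard deviation (default 0.1, about
#'   a tenth of the typical signal scale).
#' @param icScale standard deviation of the random initial conditions.
#' @param perturbMagnitudes magnitudes of the candidate-matrix
#'   perturbations (entries of A displaced by N(0, magnitude)).
#' @param samplingInterval seconds between observations.
#' @param seed integer seed; regeneration from the same seed is
#'   bit-identical.
#' @return a [SpiralDataset-class].
#' @export
makeSpiralDataset <- function(nSequences = 100L, nTimepoints = 100L,
                              A = matrix(c(-0.1, -2, 2, -0.1), 2, 2),
                              noiseSd = 0.1, icScale = 2,
                              perturbMagnitudes = c(0.3, 0.6),
                              samplingInterval = 0.1, seed = 1L) {
  if (nTimepoints < 2) stop("nTimepoints must be >= 2")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  A <- as.matrix(A)
  ev <- eigen(A, only.values = TRUE)$values
  if (all(Im(ev) == 0) || any(Re(ev) >= 0)) {
    warning("A is not an inward spiral; proceeding anyway")
  }
  withr::with_seed(as.integer(seed), {
    Phi <- as.matrix(Matrix::expm(A * samplingInterval))
    states <- vector("list", nSequences)
    observations <- vector("list", nSequences)
    for (s in seq_len(nSequences)) {
      x <- stats::rnorm(2, sd = icScale)
      S <- matrix(0, 2, nTimepoints)
      S[, 1] <- x
      for (t in 2:nTimepoints) S[, t] <- Phi %*% S[, t - 1]
      states[[s]] <- S
      observations[[s]] <- S + noiseSd * matrix(stats::rnorm(2 * nTimepoints),
                                                2, nTimepoints)
    }
    perturbedA <- lapply(perturbMagnitudes, function(m) {
      if (m == 0) A else A + matrix(stats::rnorm(4, sd = m), 2, 2)
    })
    new("SpiralDataset", A = A, perturbedA = perturbedA, states = states,
        observations = observations, noiseSd = as.numeric(noiseSd),
        samplingInterval = as.numeric(samplingInterval),
        seed = as.integer(seed))
  })
}

setMethod("show", "SpiralDataset", function(object) {
  cat(sprintf(
    "SpiralDataset: %d sequences x %d points, obs noise sd %g, dt %g s, %d candidate matrices\n",
    length(object@observations),
    if (length(object@observations)) ncol(object@observations[[1]]) else 0,
    object@noiseSd, object@samplingInterval, 1 + length(object@perturbedA)))
  invisible(object)
})

#' Generate surrogate BOLD from a known Firing Rate Model
#'
#' Per subject: simulate the FRM with known coupling `kTrue` and noise
#' `sigmaTrue` on the given (normalized) connectome from a random state,
#' discard the burn-in so the stationary regime dominates, then pass the
#' series through the full conditioning chain (bandpass, global signal
#' regression, z-scoring). The generating parameters are recorded in the
#' dataset provenance, making this the ground-truth data for
#' parameter-recovery experiments.
#'
#' Noise is essential here: without it the stable network decays to the
#' origin and the z-scoring step rightly fails on a degenerate signal, so
#' `sigmaTrue = 0` is refused up front.
#'
#' @param connectome a spectrally normalized [StructuralConnectome-class].
#' @param kTrue generating coupling, must be < 1 (stability).
#' @param sigmaTrue generating noise amplitude, must be > 0.
#' @param nSubjects number of independent subjects.
#' @param nTimepoints retained timepoints per subject.
#' @param burnIn discarded initial steps.
#' @param samplingInterval seconds per timepoint.
#' @param segmentLength training window length.
#' @param preprocess apply the conditioning chain (default TRUE).
#' @param seed integer seed.
#' @return a [TimeseriesDataset-class] with generating parameters in
#'   `provenance`.
#' @export
makeSurrogateBold <- function(connectome, kTrue = 0.9, sigmaTrue = 0.3,
                              nSubjects = 4L, nTimepoints = 500L,
                              burnIn = 100L, samplingInterval = 0.72,
                              segmentLength = 50L, preprocess = TRUE,
                              seed = 1L) {
  if (!isNormalized(connectome)) {
    stop("connectome must be spectrally normalized (see normalizeSpectral)")
  }
  if (kTrue >= 1) {
    stop("kTrue must be < 1: at k >= 1 the normalized network is unstable")
  }
  if (sigmaTrue <= 0) {
    stop("sigmaTrue must be > 0: a noiseless stable network decays to the ",
         "origin and cannot be z-scored")
  }
  n <- nRegions(connectome)
  sys <- frmModel(connectome, kTrue, sigmaTrue)
  fs <- 1 / samplingInterval
  subjectsList <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nSubjects), function(s) {
      tr <- simulateTrajectory(sys, x0 = stats::rnorm(n),
                               nSteps = burnIn + nTimepoints,
                               samplingInterval = samplingInterval)
      ts <- t(tr@states[(burnIn + 2L):(burnIn + 1L + nTimepoints), ])
      if (preprocess) preprocessChain(ts, fs) else ts
    })
  })
  timeseriesDataset(
    subjectsList, samplingInterval = samplingInterval,
    segmentLength = segmentLength,
    provenance = list(generator = "frm", kTrue = kTrue,
                      sigmaTrue = sigmaTrue, burnIn = burnIn,
                      preprocessed = isTRUE(preprocess), seed = seed))
}
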