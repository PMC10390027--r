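#' @import methods
NULL

.SYM_TOL <- 1e-10
.SPEC_TOL <- 1e-8

#' StructuralConnectome: a weighted symmetric region graph
#'
#' Holds the structural connectivity matrix \eqn{W} used by the network
#' models: a nonnegative, symmetric, zero-diagonal weight matrix over
#' cortical regions, optionally annotated with region labels and per-region
#' cortical surface areas (mm^2). After [normalizeSpectral()] the largest
#' eigenvalue of the weights is 1, so the effective system matrix
#' \eqn{kW - I} is strictly stable for coupling \eqn{k < 1}.
#'
#' @slot weights numeric matrix, symmetric, nonnegative, zero diagonal.
#' @slot regionLabels character vector of region names.
#' @slot surfaceAreas numeric vector of per-region surface areas in mm^2
#'   (length 0 when unknown).
#' @slot normalized logical; `TRUE` after spectral normalization.
#'
#' @seealso [structuralConnectome()], [normalizeSpectral()], [perturbEdges()]
#' @export
setClass("StructuralConnectome",
  slots = c(
    weights = "matrix",
    regionLabels = "character",
    surfaceAreas = "numeric",
    normalized = "logical"
  )
)

setValidity("StructuralConnectome", function(object) {
  W <- object@weights
  msg <- character()
  if (!is.numeric(W) || nrow(W) != ncol(W)) {
    return("weights must be a square numeric matrix")
  }
  n <- nrow(W)
  if (n == 0L) return(TRUE)  # empty placeholder (null-model systems)
  if (any(!is.finite(W))) msg <- c(msg, "weights contain non-finite entries")
  if (max(abs(W - t(W))) > .SYM_TOL) {
    msg <- c(msg, sprintf("weights not symmetric within %g", .SYM_TOL))
  }
  if (any(diag(W) != 0)) msg <- c(msg, "diagonal of weights must be zero")
  if (any(W < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(object@regionLabels) != n) {
    msg <- c(msg, "regionLabels length must equal number of regions")
  }
  if (length(object@surfaceAreas) &&
      (length(object@surfaceAreas) != n || any(object@surfaceAreas <= 0))) {
    msg <- c(msg, "surfaceAreas must be positive and one per region")
  }
  if (isTRUE(object@normalized)) {
    lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
    if (abs(lam - 1) > .SPEC_TOL) {
      msg <- c(msg, sprintf(
        "normalized flag set but largest eigenvalue is %.10f (tol %g)",
        lam, .SPEC_TOL))
    }
  }
  if (length(msg)) msg else TRUE
})

#' PerturbationSpec: how to randomize a connectome's edges
#'
#' A `fraction` of existing edges is moved to currently-empty node pairs
#' (weights carried over, symmetry and edge count preserved), reproducibly
#' under `seed`.
#'
#' @slot fraction proportion of upper-triangle edges to relocate, in [0, 1].
#' @slot seed integer seed driving the random relocation.
#' @export
setClass("PerturbationSpec",
  slots = c(fraction = "numeric", seed = "integer")
)

setValidity("PerturbationSpec", function(object) {
  if (length(object@fraction) != 1 || is.na(object@fraction) ||
      object@fraction < 0 || object@fraction > 1) {
    return("fraction must be a single value in [0, 1]")
  }
  TRUE
})

#' DynamicalSystem: drift specification for a network model
#'
#' One of four model kinds:
#' \describe{
#'   \item{`frm`}{Firing Rate Model \eqn{\dot x = -x + kWx + noise}, the
#'     simplest linear brain network model.}
#'   \item{`ar`}{autoregressive null: connectivity set to the identity with
#'     \eqn{k = 1}, so the drift is identically zero and the forecast is the
#'     last state.}
#'   \item{`exp_decay`}{coupling-free null \eqn{\dot x = -x} (\eqn{k = 0}).}
#'   \item{`spiral`}{planar linear system \eqn{\dot x = Ax} used for
#'     validation with known ground truth.}
#' }
#'
#' @slot kind one of "frm", "ar", "exp_decay", "spiral".
#' @slot k global coupling (dimensionless).
#' @slot sigma noise amplitude, interpreted per unit time (signal units).
#' @slot connectome a [StructuralConnectome-class] for `frm` (empty 0x0
#'   weights otherwise).
#' @slot A 2x2 drift matrix for `spiral` (0x0 otherwise).
#' @slot stateDim number of state variables.
#' @seealso [frmModel()], [arModel()], [expDecayModel()], [spiralModel()]
#' @export
setClass("DynamicalSystem",
  slots = c(
    kind = "character",
    k = "numeric",
    sigma = "numeric",
    connectome = "StructuralConnectome",
    A = "matrix",
    stateDim = "integer"
  )
)

setValidity("DynamicalSystem", function(object) {
  msg <- character()
  if (!object@kind %in% c("frm", "ar", "exp_decay", "spiral")) {
    return("kind must be one of frm, ar, exp_decay, spiral")
  }
  if (object@k < 0) msg <- c(msg, "k must be >= 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@kind == "frm" &&
      nrow(object@connectome@weights) != object@stateDim) {
    msg <- c(msg, "frm system needs a connectome matching stateDim")
  }
  if (object@kind == "ar" && object@k != 1) {
    msg <- c(msg, "ar null requires k = 1 (identity connectivity)")
  }
  if (object@kind == "exp_decay" && object@k != 0) {
    msg <- c(msg, "exp_decay null requires k = 0")
  }
  if (object@kind == "spiral" &&
      (!all(dim(object@A) == c(2L, 2L)) || object@stateDim != 2L)) {
    msg <- c(msg, "spiral system requires a 2x2 A matrix and stateDim 2")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: a uniformly sampled state sequence
#'
#' @slot states T x n matrix of states, one row per sampled time.
#' @slot samplingInterval seconds between consecutive rows.
#' @slot t0 time of the first row, seconds.
#' @export
setClass("Trajectory",
  slots = c(states = "matrix", samplingInterval = "numeric", t0 = "numeric")
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (nrow(object@states) < 1) msg <- c(msg, "states must have >= 1 row")
  if (object@samplingInterval <= 0) msg <- c(msg, "samplingInterval must be > 0")
  if (any(!is.finite(object@states))) msg <- c(msg, "states contain non-finite entries")
  if (length(msg)) msg else TRUE
})

#' TimeseriesDataset: a collection of region x time recordings
#'
#' All subjects share the same region count and sampling interval;
#' `segmentLength` controls how series are cut into fixed-length training
#' windows (trailing remainder dropped).
#'
#' @slot subjects list of region x time numeric matrices.
#' @slot samplingInterval seconds per timepoint.
#' @slot segmentLength window length in timepoints (default 50).
#' @slot provenance free-form list describing how the data were produced
#'   (generator parameters, seeds, preprocessing applied).
#' @export
setClass("TimeseriesDataset",
  slots = c(
    subjects = "list",
    samplingInterval = "numeric",
    segmentLength = "integer",
    provenance = "list"
  )
)

setValidity("TimeseriesDataset", function(object) {
  msg <- character()
  if (!length(object@subjects)) msg <- c(msg, "no subjects")
  ns <- vapply(object@subjects, nrow, 1L)
  if (length(unique(ns)) > 1) msg <- c(msg, "subjects differ in region count")
  if (object@samplingInterval <= 0) msg <- c(msg, "samplingInterval must be > 0")
  if (object@segmentLength < 2) msg <- c(msg, "segmentLength must be >= 2")
  if (length(msg)) msg else TRUE
})

#' EstimatorConfig: hyperparameters of the recurrent IC estimator
#'
#' @slot hiddenSize LSTM hidden units per layer.
#' @slot nLayers number of stacked LSTM layers.
#' @slot learningRate Adam step size.
#' @slot nEpochs maximum training epochs.
#' @slot batchSize sequences per minibatch.
#' @slot warmup number of prefix observations consumed before predictions
#'   are scored in the loss (and before inference anchors are allowed).
#' @slot patience epochs without improvement before early stopping.
#' @slot distributional if `TRUE` the network also outputs a per-region
#'   log-variance so its next-step prediction is a diagonal Gaussian
#'   (required by the autoregressive inference null, [inferenceRollout()]).
#' @slot seed integer seed for initialization and minibatch shuffling.
#' @seealso [estimatorConfig()]
#' @export
setClass("EstimatorConfig",
  slots = c(
    hiddenSize = "integer", nLayers = "integer", learningRate = "numeric",
    nEpochs = "integer", batchSize = "integer", warmup = "integer",
    patience = "integer", distributional = "logical", seed = "integer"
  )
)

setValidity("EstimatorConfig", function(object) {
  counts <- c(object@hiddenSize, object@nLayers, object@nEpochs,
              object@batchSize, object@warmup, object@patience)
  if (any(counts < 1)) return("all counts must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  TRUE
})

#' TrainedEstimator: an IC estimator bound to one dynamical system
#'
#' One estimator is trained per (k, W) system; it refuses to run against a
#' different system (fingerprint check).
#'
#' @slot config the [EstimatorConfig-class] used in training.
#' @slot system the [DynamicalSystem-class] the estimator was trained for.
#' @slot weights list of LSTM and output-head parameter matrices.
#' @slot lossCurve per-epoch training losses.
#' @slot samplingInterval seconds per observation the estimator was
#'   trained at (fixes the one-step propagator).
#' @slot fingerprint system fingerprint recorded at training time.
#' @export
setClass("TrainedEstimator",
  slots = c(
    config = "EstimatorConfig",
    system = "DynamicalSystem",
    weights = "list",
    lossCurve = "numeric",
    samplingInterval = "numeric",
    fingerprint = "character"
  )
)

#' HorizonScores: per-horizon prediction accuracy
#'
#' @slot scores data.frame with columns `trial`, `subject`, `tIndex`,
#'   `horizon`, `r2`, `mse`.
#' @slot aggregation "group" (errors pooled over a batch of subjects before
#'   scoring) or "individual" (one score per subject/timepoint).
#' @slot nTrials number of distinct trials per horizon.
#' @export
setClass("HorizonScores",
  slots = c(scores = "data.frame", aggregation = "character",
            nTrials = "integer")
)

#' SweepResult: scores over a (coupling x noise x perturbation) grid
#'
#' @slot scores long-format data.frame of mean scores per grid cell.
#' @slot slopes data.frame of structural-sensitivity slopes per (k, sigma).
#' @slot argmax list naming the selected cell and its score.
#' @slot axes list of the grid axes actually swept.
#' @export
setClass("SweepResult",
  slots = c(scores = "data.frame", slopes = "data.frame",
            argmax = "list", axes = "list")
)

#' SpiralDataset: noisy observations of a planar spiral with known truth
#'
#' @slot A true 2x2 drift matrix.
#' @slot perturbedA list of perturbed drift matrices (increasing magnitude).
#' @slot states list of noiseless 2 x T state matrices (ground truth).
#' @slot observations list of noisy 2 x T observation matrices.
#' @slot noiseSd observation noise standard deviation.
#' @slot samplingInterval seconds between observations.
#' @slot seed generator seed.
#' @export
setClass("SpiralDataset",
  slots = c(
    A = "matrix", perturbedA = "list", states = "list",
    observations = "list", noiseSd = "numeric",
    samplingInterval = "numeric", seed = "integer"
  )
)

setValidity("SpiralDataset", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@observations) &&
      any(vapply(object@observations, ncol, 1L) < 2)) {
    msg <- c(msg, "each sequence needs >= 2 observations")
  }
  if (length(msg)) msg else TRUE
})
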