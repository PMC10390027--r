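#' @include lstm.R dynamics.R preprocess.R
NULL

#' Configure the recurrent initial-condition estimator
#'
#' Defaults are sized to converge on a desktop CPU at fixture scale
#' (tens of regions, tens of 50-point windows): a single LSTM layer of 64
#' hidden units, Adam at 1e-3, early stopping after 10 epochs without
#' improvement. `warmup` observations are consumed before predictions
#' enter the loss, giving the hidden state time to synchronize.
#'
#' @param hiddenSize LSTM hidden units.
#' @param nLayers stacked LSTM layers.
#' @param learningRate Adam step size.
#' @param nEpochs maximum epochs.
#' @param batchSize sequences per minibatch.
#' @param warmup prefix observations before predictions are scored.
#' @param patience early-stopping patience in epochs.
#' @param distributional add a per-region log-variance head (needed only
#'   for the [inferenceRollout()] null model).
#' @param seed integer seed for initialization and shuffling.
#' @return an [EstimatorConfig-class].
#' @export
estimatorConfig <- function(hiddenSize = 64L, nLayers = 1L,
                            learningRate = 1e-3, nEpochs = 100L,
                            batchSize = 32L, warmup = 10L, patience = 10L,
                            distributional = FALSE, seed = 1L) {
  new("EstimatorConfig", hiddenSize = as.integer(hiddenSize),
      nLayers = as.integer(nLayers), learningRate = as.numeric(learningRate),
      nEpochs = as.integer(nEpochs), batchSize = as.integer(batchSize),
      warmup = as.integer(warmup), patience = as.integer(patience),
      distributional = isTRUE(distributional), seed = as.integer(seed))
}

.systemFingerprint <- function(system) {
  W <- .driftMatrix(system)
  paste(system@kind, system@stateDim, format(system@k, digits = 15),
        format(sum(W), digits = 15), format(sum(W * W), digits = 15),
        sep = "|")
}

.asSegments <- function(dataset) {
  if (is(dataset, "TimeseriesDataset")) .datasetSegments(dataset)$segments
  else if (is(dataset, "SpiralDataset")) dataset@observations
  else if (is.list(dataset)) dataset
  else stop("dataset must be a TimeseriesDataset, SpiralDataset or list of matrices")
}

#' Train an initial-condition estimator for one dynamical system
#'
#' A forward-time LSTM consumes the observed series one timepoint at a
#' time (teacher forcing) and at every timepoint outputs a candidate state
#' of the given system. The loss is the mean squared error between the
#' next observation and the one-interval noiseless propagation of that
#' candidate state, so minimizing it drives the output toward the state
#' that best synchronizes the model with the data. Training never uses the
#' model's noise term. One estimator is bound to one (k, W) system.
#'
#' @param dataset a [TimeseriesDataset-class], [SpiralDataset-class], or a
#'   list of region x length matrices (all equal length).
#' @param system the [DynamicalSystem-class] to synchronize (kinds frm, ar,
#'   exp_decay for network data; spiral for validation data).
#' @param config an [EstimatorConfig-class].
#' @param samplingInterval seconds per observation; taken from the dataset
#'   when it carries one.
#' @return a [TrainedEstimator-class].
#' @export
trainEstimator <- function(dataset, system, config = estimatorConfig(),
                           samplingInterval = NULL) {
  if (is.null(samplingInterval)) {
    samplingInterval <- if (is(dataset, "TimeseriesDataset")) dataset@samplingInterval
      else if (is(dataset, "SpiralDataset")) dataset@samplingInterval
      else 0.72
  }
  segments <- .asSegments(dataset)
  n <- nrow(segments[[1]])
  if (n != system@stateDim) {
    stop("data has ", n, " regions but system expects ", system@stateDim)
  }
  Phi <- propagator(system, samplingInterval)
  fit <- .lstmTrain(segments, Phi, n, config)
  if (length(fit$lossCurve) > 1 &&
      fit$lossCurve[length(fit$lossCurve)] >= fit$lossCurve[1]) {
    warning("training loss did not decrease; inspect the loss curve")
  }
  new("TrainedEstimator", config = config, system = system,
      weights = fit$par, lossCurve = fit$lossCurve,
      samplingInterval = samplingInterval,
      fingerprint = .systemFingerprint(system))
}

setMethod("show", "TrainedEstimator", function(object) {
  lc <- object@lossCurve
  cat(sprintf(
    "TrainedEstimator for <%s> (k = %g, %d regions): %d epochs, loss %.4g -> %.4g\n",
    object@system@kind, object@system@k, object@system@stateDim,
    length(lc), lc[1], lc[length(lc)]))
  invisible(object)
})

.checkSystem <- function(est, system) {
  if (!identical(est@fingerprint, .systemFingerprint(system))) {
    stop("estimator was trained for a different system ",
         "(fingerprint mismatch); train one estimator per (k, W) pair")
  }
}

#' Estimate the system state from an observation prefix
#'
#' Feeds the prefix through the trained LSTM and returns its final output:
#' the model state at the time of the last observation. Estimates improve
#' as the prefix grows, up to a plateau.
#'
#' @param est a [TrainedEstimator-class].
#' @param prefix region x t matrix of observations, t >= 1.
#' @return state vector (length stateDim).
#' @export
estimateIC <- function(est, prefix) {
  prefix <- as.matrix(prefix)
  if (ncol(prefix) < 1 || nrow(prefix) != est@system@stateDim) {
    stop("prefix must be a ", est@system@stateDim, " x t matrix with t >= 1")
  }
  X <- array(prefix, c(nrow(prefix), ncol(prefix), 1L))
  fw <- .lstmForward(est@weights, X, needCache = FALSE)
  as.numeric(.sl(fw$Y, ncol(prefix)))
}

# Exact discretized noise for one sampled interval of a linear system:
# returns a function(B) drawing n x B noise increments with the stationary
# Ornstein-Uhlenbeck step covariance (symmetric kinds), or by sub-stepped
# accumulation for the non-symmetric spiral drift.
.noiseSampler <- function(system, dt, sigma, substeps = 10L) {
  n <- system@stateDim
  if (sigma == 0) return(function(B) matrix(0, n, B))
  eig <- .driftEigen(system)
  if (!is.null(eig)) {
    a <- eig$values
    v <- ifelse(abs(a) < 1e-12, sigma^2 * dt,
                sigma^2 * (exp(2 * a * dt) - 1) / (2 * a))
    sdv <- sqrt(v)
    V <- eig$vectors
    function(B) V %*% (sdv * matrix(stats::rnorm(n * B), n, B))
  } else {
    dts <- dt / substeps
    E <- as.matrix(Matrix::expm(system@A * dts))
    sdW <- sigma * sqrt(dts)
    function(B) {
      eta <- matrix(0, n, B)
      for (j in seq_len(substeps)) {
        eta <- E %*% eta + sdW * matrix(stats::rnorm(n * B), n, B)
      }
      eta
    }
  }
}

#' Predict forward from an estimated initial condition
#'
#' Estimates the state at `tIndex` from the segment prefix, then
#' propagates the system forward `horizon` sampled steps with evaluation
#' noise `sigma`. Row h of the result is the prediction aligned with
#' `segment[, tIndex + h]`.
#'
#' @param est a [TrainedEstimator-class].
#' @param segment region x length observation matrix.
#' @param tIndex anchor timepoint (>= the training warmup).
#' @param horizon number of sampled steps to predict.
#' @param sigma evaluation noise amplitude (0 for deterministic).
#' @param seed integer seed, or `NULL` for the current stream.
#' @return horizon x regions matrix of predicted states.
#' @export
predictHorizon <- function(est, segment, tIndex, horizon, sigma = 0,
                           seed = NULL) {
  segment <- as.matrix(segment)
  if (tIndex < est@config@warmup) {
    stop("tIndex must be >= the training warmup (", est@config@warmup, ")")
  }
  if (tIndex + horizon > ncol(segment)) {
    stop("horizon extends past the segment (tIndex + horizon > ",
         ncol(segment), ")")
  }
  ic <- estimateIC(est, segment[, seq_len(tIndex), drop = FALSE])
  dt <- est@samplingInterval
  Phi <- propagator(est@system, dt)
  run <- function() {
    noise <- .noiseSampler(est@system, dt, sigma)
    out <- matrix(NA_real_, horizon, length(ic))
    x <- ic
    for (h in seq_len(horizon)) {
      x <- as.numeric(Phi %*% x + noise(1L))
      out[h, ] <- x
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Autoregressive inference rollout (machine-learning null)
#'
#' For an estimator trained with a distributional head, rolls the network
#' forward autoregressively: after consuming the prefix, each next input
#' is *sampled* from the network's predicted next-observation distribution
#' (diagonal Gaussian with input-dependent variance) and fed back in. The
#' model dynamics are entirely the network's own; this serves as an
#' empirical upper bound on short-window predictability.
#'
#' @param est a [TrainedEstimator-class] with `distributional = TRUE`.
#' @param prefix region x t observation matrix.
#' @param horizon steps to roll out (0 gives an empty prediction).
#' @param seed integer seed, or `NULL`.
#' @return horizon x regions matrix of sampled observations.
#' @export
inferenceRollout <- function(est, prefix, horizon, seed = NULL) {
  if (!est@config@distributional) {
    stop("inferenceRollout needs an estimator trained with a distributional ",
         "output head (see estimatorConfig(distributional = TRUE))")
  }
  prefix <- as.matrix(prefix)
  n <- est@system@stateDim
  if (nrow(prefix) != n || ncol(prefix) < 1) {
    stop("prefix must be a ", n, " x t matrix with t >= 1")
  }
  if (horizon == 0) return(matrix(numeric(0), 0, n))
  Phi <- propagator(est@system, est@samplingInterval)
  run <- function() {
    X <- array(prefix, c(n, ncol(prefix), 1L))
    fw <- .lstmForward(est@weights, X, needCache = FALSE)
    st <- fw$state
    y <- .sl(fw$Y, ncol(prefix)); lv <- .sl(fw$LV, ncol(prefix))
    out <- matrix(NA_real_, horizon, n)
    for (h in seq_len(horizon)) {
      mu <- Phi %*% y
      xNext <- mu + exp(lv / 2) * stats::rnorm(n)
      out[h, ] <- xNext
      fw <- .lstmForward(est@weights, array(xNext, c(n, 1L, 1L)),
                         state = st, needCache = FALSE)
      st <- fw$state
      y <- .sl(fw$Y, 1L); lv <- .sl(fw$LV, 1L)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
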