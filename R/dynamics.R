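#' @include connectome.R
NULL

.emptyConn <- function() {
  new("StructuralConnectome", weights = matrix(numeric(0), 0, 0),
      regionLabels = character(0), surfaceAreas = numeric(0),
      normalized = FALSE)
}

#' Firing Rate Model
#'
#' The linear brain network model \eqn{\dot x_i = -x_i + k \sum_j W_{ij} x_j
#' + N(0, \sigma)}: each region's firing rate decays at unit rate and is
#' driven by the weighted sum of its structural neighbors, scaled by the
#' global coupling `k`. With a spectrally normalized `W` the system is
#' stable for `k < 1` ([stabilityMargin()]).
#'
#' @param connectome a [StructuralConnectome-class].
#' @param k global coupling, >= 0.
#' @param sigma noise amplitude per unit time (used in simulation and
#'   evaluation, never in estimator training).
#' @return a [DynamicalSystem-class] of kind "frm".
#' @export
frmModel <- function(connectome, k, sigma = 0) {
  new("DynamicalSystem", kind = "frm", k = as.numeric(k),
      sigma = as.numeric(sigma), connectome = connectome,
      A = matrix(numeric(0), 0, 0), stateDim = nRegions(connectome))
}

#' Autoregressive null model
#'
#' Connectivity set to the identity with \eqn{k = 1}: the network term
#' cancels the decay, the drift is identically zero, and the noiseless
#' forecast holds the current state, \eqn{x(n+1) = x(n)}.
#'
#' @param n state dimension (or a [StructuralConnectome-class] to copy it from).
#' @param sigma noise amplitude per unit time.
#' @return a [DynamicalSystem-class] of kind "ar".
#' @export
arModel <- function(n, sigma = 0) {
  if (is(n, "StructuralConnectome")) n <- nRegions(n)
  new("DynamicalSystem", kind = "ar", k = 1, sigma = as.numeric(sigma),
      connectome = .emptyConn(), A = matrix(numeric(0), 0, 0),
      stateDim = as.integer(n))
}

#' Exponential-decay null model
#'
#' Global coupling set to zero: every region decays independently,
#' \eqn{\dot x = -x}. Tests the limit of no network influence.
#'
#' @inheritParams arModel
#' @return a [DynamicalSystem-class] of kind "exp_decay".
#' @export
expDecayModel <- function(n, sigma = 0) {
  if (is(n, "StructuralConnectome")) n <- nRegions(n)
  new("DynamicalSystem", kind = "exp_decay", k = 0, sigma = as.numeric(sigma),
      connectome = .emptyConn(), A = matrix(numeric(0), 0, 0),
      stateDim = as.integer(n))
}

#' Planar spiral system
#'
#' Two-variable linear system \eqn{\dot x = Ax}; with complex eigenvalues
#' of negative real part the trajectories spiral into the origin. Used as
#' the validation system with known ground truth.
#'
#' @param A 2x2 drift matrix; the default spirals inward with angular
#'   frequency 2 rad/s and decay rate 0.1/s.
#' @param sigma process noise amplitude per unit time.
#' @return a [DynamicalSystem-class] of kind "spiral".
#' @export
spiralModel <- function(A = matrix(c(-0.1, -2, 2, -0.1), 2, 2), sigma = 0) {
  A <- as.matrix(A)
  ev <- eigen(A, only.values = TRUE)$values
  if (all(Im(ev) == 0) || any(Re(ev) >= 0)) {
    warning("A does not define an inward spiral ",
            "(expect complex eigenvalues with negative real part)")
  }
  new("DynamicalSystem", kind = "spiral", k = 0, sigma = as.numeric(sigma),
      connectome = .emptyConn(), A = A, stateDim = 2L)
}

setMethod("nRegions", "DynamicalSystem", function(x) x@stateDim)

setMethod("show", "DynamicalSystem", function(object) {
  cat(sprintf("DynamicalSystem <%s>: %d state variables, k = %g, sigma = %g\n",
              object@kind, object@stateDim, object@k, object@sigma))
  invisible(object)
})

# drift matrix A such that dx/dt = A x (all implemented kinds are linear)
.driftMatrix <- function(system) {
  n <- system@stateDim
  switch(system@kind,
    frm = system@k * system@connectome@weights - diag(n),
    ar = matrix(0, n, n),
    exp_decay = -diag(n),
    spiral = system@A
  )
}

# eigendecomposition of the drift for the symmetric kinds, NULL for spiral
.driftEigen <- function(system) {
  if (system@kind == "spiral") return(NULL)
  n <- system@stateDim
  if (system@kind == "frm") {
    e <- eigen(system@connectome@weights, symmetric = TRUE)
    list(values = system@k * e$values - 1, vectors = e$vectors)
  } else if (system@kind == "ar") {
    list(values = rep(0, n), vectors = diag(n))
  } else {
    list(values = rep(-1, n), vectors = diag(n))
  }
}

#' One-interval propagator matrix
#'
#' The exact linear flow \eqn{\Phi = e^{A \Delta t}} of the noiseless
#' system over `dt` seconds (with \eqn{A = kW - I}, \eqn{0}, \eqn{-I} or
#' the spiral matrix depending on kind). This is the map used inside the
#' estimator's one-step training loss.
#'
#' @param system a [DynamicalSystem-class].
#' @param dt step length in seconds.
#' @return stateDim x stateDim matrix.
#' @export
propagator <- function(system, dt) {
  eig <- .driftEigen(system)
  if (is.null(eig)) {
    return(as.matrix(Matrix::expm(system@A * dt)))
  }
  V <- eig$vectors
  V %*% (exp(eig$values * dt) * t(V))
}

#' @rdname drift
#' @export
setMethod("drift", "DynamicalSystem", function(system, x) {
  if (length(x) != system@stateDim) {
    stop("state has length ", length(x), ", expected ", system@stateDim)
  }
  as.numeric(.driftMatrix(system) %*% x)
})

.OVERFLOW_GUARD <- 1e6

#' Simulate a stochastic trajectory
#'
#' Integrates the system over `nSteps` sampled intervals of
#' `samplingInterval` seconds, emitting one state per interval (the initial
#' state is row 1). Each interval is split into `substeps`; per substep the
#' drift is advanced and a noise increment \eqn{\sigma \sqrt{dt}\, N(0,1)}
#' is added per state variable, so `sigma` is interpreted per unit time.
#'
#' Two drift schemes are available. `"exact"` (default) advances the
#' linear drift with the matrix-exponential substep propagator, so the
#' noiseless path matches [closedFormLinear()] to machine precision;
#' `"euler"` is the plain Euler-Maruyama update, kept for order checks and
#' as the template for non-linear drifts.
#'
#' @param system a [DynamicalSystem-class] (its `sigma` is used unless
#'   overridden).
#' @param x0 initial state vector.
#' @param nSteps number of sampled steps (>= 1).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param samplingInterval seconds per emitted step; the default 0.72 s is
#'   the repetition time of the targeted fMRI acquisitions.
#' @param sigma optional noise amplitude override.
#' @param substeps integration substeps per sampled interval.
#' @param scheme "exact" or "euler".
#' @param t0 time of the initial state.
#' @return a [Trajectory-class] with `nSteps + 1` rows.
#' @examples
#' sys <- expDecayModel(1)
#' states(simulateTrajectory(sys, 1, 1))[2, ]  # ~ exp(-0.72)
#' @export
simulateTrajectory <- function(system, x0, nSteps, seed = NULL,
                               samplingInterval = 0.72, sigma = NULL,
                               substeps = 10L, scheme = c("exact", "euler"),
                               t0 = 0) {
  scheme <- match.arg(scheme)
  if (nSteps < 1) stop("nSteps must be >= 1")
  if (length(x0) != system@stateDim) {
    stop("x0 has length ", length(x0), ", expected ", system@stateDim)
  }
  if (is.null(sigma)) sigma <- system@sigma
  run <- function() {
    n <- system@stateDim
    dt <- samplingInterval / substeps
    A <- .driftMatrix(system)
    E <- if (scheme == "exact") propagator(system, dt) else diag(n) + A * dt
    sdW <- sigma * sqrt(dt)
    out <- matrix(NA_real_, nSteps + 1L, n)
    x <- as.numeric(x0)
    out[1L, ] <- x
    for (s in seq_len(nSteps)) {
      for (j in seq_len(substeps)) {
        x <- as.numeric(E %*% x)
        if (sdW > 0) x <- x + sdW * stats::rnorm(n)
      }
      if (any(abs(x) > .OVERFLOW_GUARD)) {
        stop("trajectory overflow (|state| > 1e6) at sampled step ", s,
             ": unstable parameterization?")
      }
      out[s + 1L, ] <- x
    }
    new("Trajectory", states = out, samplingInterval = samplingInterval,
        t0 = t0)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Closed-form state of a noiseless linear system
#'
#' Returns \eqn{e^{At} x_0} for the linear kinds (frm with sigma ignored,
#' exp_decay, spiral); this is the analytic oracle against which the
#' integrator is validated.
#'
#' @param system a [DynamicalSystem-class]; kind "ar" is refused (the null
#'   is defined by its forecasting rule, not by a flow).
#' @param x0 initial state.
#' @param t elapsed time in seconds.
#' @return state vector at time t.
#' @export
closedFormLinear <- function(system, x0, t) {
  if (system@kind == "ar") {
    stop("closedFormLinear is unsupported for the ar null model")
  }
  if (length(x0) != system@stateDim) {
    stop("x0 has length ", length(x0), ", expected ", system@stateDim)
  }
  as.numeric(propagator(system, t) %*% x0)
}

#' Surface-area-scaled noise amplitude
#'
#' Per-parcel noise standard deviation proportional to cortical surface
#' area: \eqn{\sigma = 0.35 \cdot area / 858}, anchored at the mean parcel
#' area of 858 mm^2 of the 66-region cortical parcellation.
#'
#' @param surfaceArea parcel surface area(s) in mm^2, > 0.
#' @return noise standard deviation(s) in signal units.
#' @examples
#' areaScaledSigma(858)  # 0.35
#' @export
areaScaledSigma <- function(surfaceArea) {
  if (any(!is.finite(surfaceArea)) || any(surfaceArea <= 0)) {
    stop("surfaceArea must be positive")
  }
  0.35 * (surfaceArea / 858)
}

#' @rdname states
#' @export
setMethod("states", "Trajectory", function(x) x@states)

#' @rdname samplingInterval
#' @export
setMethod("samplingInterval", "Trajectory", function(x) x@samplingInterval)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d timepoints x %d variables, dt = %g s (t0 = %g)\n",
              nrow(object@states), ncol(object@states),
              object@samplingInterval, object@t0))
  invisible(object)
})
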