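#' @include AllClasses.R
NULL

#' Number of regions
#' @param x a [StructuralConnectome-class], [DynamicalSystem-class] or
#'   [TimeseriesDataset-class].
#' @return integer count of regions / state variables.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Connectome weight matrix
#' @param x a [StructuralConnectome-class].
#' @return the symmetric weight matrix.
#' @export
setGeneric("scWeights", function(x) standardGeneric("scWeights"))

#' Region labels
#' @param x an object carrying region labels.
#' @return character vector.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Per-region cortical surface areas (mm^2)
#' @param x a [StructuralConnectome-class].
#' @return numeric vector (length 0 when unknown).
#' @export
setGeneric("surfaceAreas", function(x) standardGeneric("surfaceAreas"))

#' Replace per-region surface areas
#' @param x a [StructuralConnectome-class].
#' @param value positive numeric vector, one entry per region.
#' @export
setGeneric("surfaceAreas<-", function(x, value) standardGeneric("surfaceAreas<-"))

#' Has the connectome been spectrally normalized?
#' @param x a [StructuralConnectome-class].
#' @return logical.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Divide connectome weights by their largest eigenvalue
#'
#' After normalization the largest eigenvalue of \eqn{W} is 1, so for any
#' coupling \eqn{k < 1} every eigenvalue of \eqn{kW - I} is negative and
#' the noiseless network decays to the origin.
#'
#' @param conn a [StructuralConnectome-class] with nonzero weights.
#' @return the normalized connectome (idempotent).
#' @examples
#' conn <- structuralConnectome(matrix(c(0, 2, 2, 0), 2))
#' scWeights(normalizeSpectral(conn))
#' @export
setGeneric("normalizeSpectral", function(conn) standardGeneric("normalizeSpectral"))

#' Randomly relocate a fraction of connectome edges
#'
#' A fraction of the existing (upper-triangle) edges is moved to
#' currently-empty node pairs, carrying their weights, keeping the matrix
#' symmetric and the edge count unchanged. Used to build null networks of
#' increasing distance from the measured structural connectivity.
#'
#' @param conn a [StructuralConnectome-class].
#' @param spec a [PerturbationSpec-class], or a numeric fraction in [0, 1].
#' @param ... for the numeric method: `seed`, an integer seed (or `NULL`
#'   to draw from the current RNG stream).
#' @return a perturbed [StructuralConnectome-class] (`normalized` flag
#'   dropped: relocation changes the spectrum).
#' @export
setGeneric("perturbEdges", function(conn, spec, ...) standardGeneric("perturbEdges"))

#' Stability margin of the coupled system
#'
#' Largest real part over eigenvalues of \eqn{kW - I}; negative means the
#' noiseless network decays. For a spectrally normalized connectome this is
#' exactly \eqn{k - 1}.
#'
#' @param conn a [StructuralConnectome-class].
#' @param k global coupling.
#' @return a single numeric margin.
#' @export
setGeneric("stabilityMargin", function(conn, k) standardGeneric("stabilityMargin"))

#' Model drift (instantaneous rate of change)
#' @param system a [DynamicalSystem-class].
#' @param x state vector of length `stateDim`.
#' @return rate vector of the same length.
#' @export
setGeneric("drift", function(system, x) standardGeneric("drift"))

#' Sampled states of a Trajectory
#' @param x a [Trajectory-class].
#' @return T x n matrix.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Sampling interval in seconds
#' @param x a [Trajectory-class] or [TimeseriesDataset-class].
#' @return numeric seconds per sampled step.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' Subject matrices of a dataset
#' @param x a [TimeseriesDataset-class].
#' @return list of region x time matrices.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
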