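#' @include AllGenerics.R
NULL

#' Construct a TimeseriesDataset
#'
#' @param subjects list of region x time numeric matrices (or a single
#'   matrix).
#' @param samplingInterval seconds per timepoint (default 0.72, the
#'   repetition time of the targeted acquisitions).
#' @param segmentLength training window length in timepoints.
#' @param provenance free-form list recording how the data were produced.
#' @return a [TimeseriesDataset-class].
#' @export
timeseriesDataset <- function(subjects, samplingInterval = 0.72,
                              segmentLength = 50L, provenance = list()) {
  if (is.matrix(subjects)) subjects <- list(subjects)
  new("TimeseriesDataset", subjects = subjects,
      samplingInterval = as.numeric(samplingInterval),
      segmentLength = as.integer(segmentLength), provenance = provenance)
}

#' @rdname subjects
#' @export
setMethod("subjects", "TimeseriesDataset", function(x) x@subjects)

#' @rdname samplingInterval
#' @export
setMethod("samplingInterval", "TimeseriesDataset", function(x) x@samplingInterval)

#' @rdname nRegions
#' @export
setMethod("nRegions", "TimeseriesDataset", function(x) nrow(x@subjects[[1]]))

setMethod("show", "TimeseriesDataset", function(object) {
  Ts <- vapply(object@subjects, ncol, 1L)
  cat(sprintf(
    "TimeseriesDataset: %d subject(s), %d regions, %s timepoints, dt = %g s\n",
    length(object@subjects), nRegions(object),
    paste(unique(Ts), collapse = "/"), object@samplingInterval))
  if (length(object@provenance)) {
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
  }
  invisible(object)
})

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth bandpass applied forward-backward
#' ([signal::filtfilt()]) to each region's series, so the filter is
#' zero-phase. Each region is demeaned first: at the default low cutoff of
#' 0.0008 Hz the high-pass transition is far slower than any realistic
#' record length, so the DC offset is removed explicitly rather than by
#' the filter.
#'
#' @param ts region x time numeric matrix.
#' @param fs sampling frequency in Hz.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return filtered matrix of the same shape.
#' @export
bandpassFilter <- function(ts, fs, lo = 0.0008, hi = 0.125) {
  if (lo <= 0) stop("low cutoff must be > 0")
  if (hi <= lo) stop("high cutoff must exceed low cutoff")
  if (hi >= fs / 2) {
    stop(sprintf("high cutoff %g Hz must be below Nyquist %g Hz", hi, fs / 2))
  }
  ny <- fs / 2
  bf <- signal::butter(4, c(lo, hi) / ny, type = "pass")
  out <- ts - rowMeans(ts)
  for (i in seq_len(nrow(out))) {
    out[i, ] <- signal::filtfilt(bf, out[i, ])
  }
  out
}

#' Global signal regression
#'
#' Regresses the mean timeseries over all regions (the "global signal")
#' out of every region by ordinary least squares with an intercept; each
#' region is replaced by its residual, which is orthogonal to the global
#' signal.
#'
#' @param ts region x time numeric matrix with >= 2 regions.
#' @return residual matrix of the same shape.
#' @export
regressGlobalSignal <- function(ts) {
  if (nrow(ts) < 2) stop("global signal regression needs >= 2 regions")
  g <- colMeans(ts)
  if (stats::sd(g) < 1e-12) {
    stop("global signal is constant: degenerate regressor")
  }
  X <- cbind(1, g)
  beta <- qr.coef(qr(X), t(ts))         # 2 x regions
  ts - t(X %*% beta)
}

#' Z-score each region
#'
#' Centers and scales each region to mean 0, standard deviation 1. The
#' population (1/N) denominator is used. Set `margin = "global"` to use a
#' single mean/sd over the whole matrix instead.
#'
#' @param ts region x time numeric matrix.
#' @param margin "region" (default) or "global".
#' @return z-scored matrix.
#' @export
zscoreRegions <- function(ts, margin = c("region", "global")) {
  margin <- match.arg(margin)
  if (margin == "global") {
    s <- stats::sd(as.numeric(ts)) * sqrt((length(ts) - 1) / length(ts))
    if (!is.finite(s) || s == 0) stop("zero overall variance")
    return((ts - mean(ts)) / s)
  }
  m <- rowMeans(ts)
  s <- sqrt(rowMeans((ts - m)^2))       # population sd
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  (ts - m) / s
}

#' Cut a series into fixed-length segments
#'
#' Non-overlapping consecutive windows of `length` timepoints; the series
#' is truncated to the closest multiple of `length` (trailing remainder
#' dropped).
#'
#' @param ts region x time numeric matrix.
#' @param length window length in timepoints.
#' @return list of region x length matrices.
#' @export
segmentTimeseries <- function(ts, length = 50L) {
  T <- ncol(ts)
  if (T < length) {
    stop("series has ", T, " timepoints, shorter than segment length ", length)
  }
  nSeg <- T %/% length
  lapply(seq_len(nSeg), function(s) {
    ts[, ((s - 1L) * length + 1L):(s * length), drop = FALSE]
  })
}

#' The full BOLD conditioning chain
#'
#' Bandpass (0.0008-0.125 Hz, zero-phase) -> global signal regression ->
#' per-region z-scoring, in that order. Applied identically to measured
#' and surrogate data.
#'
#' @param ts region x time numeric matrix.
#' @param fs sampling frequency in Hz.
#' @param lo,hi band edges in Hz.
#' @return conditioned matrix, per-region mean 0 and sd 1.
#' @export
preprocessChain <- function(ts, fs, lo = 0.0008, hi = 0.125) {
  zscoreRegions(regressGlobalSignal(bandpassFilter(ts, fs, lo, hi)))
}

#' Apply the conditioning chain to every subject of a dataset
#'
#' @param dataset a [TimeseriesDataset-class].
#' @param lo,hi band edges in Hz.
#' @return a new [TimeseriesDataset-class]; provenance records the chain.
#' @export
preprocessDataset <- function(dataset, lo = 0.0008, hi = 0.125) {
  fs <- 1 / dataset@samplingInterval
  dataset@subjects <- lapply(dataset@subjects, preprocessChain,
                             fs = fs, lo = lo, hi = hi)
  dataset@provenance <- c(dataset@provenance,
                          list(preprocess = list(lo = lo, hi = hi,
                                                 chain = "bandpass+gsr+zscore")))
  dataset
}

# all fixed-length segments of a dataset, as a flat list with subject ids
.datasetSegments <- function(dataset) {
  segs <- list(); subj <- integer(0)
  for (i in seq_along(dataset@subjects)) {
    si <- segmentTimeseries(dataset@subjects[[i]], dataset@segmentLength)
    segs <- c(segs, si)
    subj <- c(subj, rep(i, length(si)))
  }
  list(segments = segs, subject = subj)
}

#' Interleave segments from two datasets
#'
#' Alternates windows from two sources (e.g. rest and task surrogates) for
#' training on more varied data. Lengths need not match; the longer tail
#' is appended.
#'
#' @param a,b [TimeseriesDataset-class] objects with equal region counts
#'   and sampling intervals.
#' @return flat list of region x segmentLength matrices.
#' @export
interleaveSegments <- function(a, b) {
  if (nRegions(a) != nRegions(b) ||
      a@samplingInterval != b@samplingInterval) {
    stop("datasets must share region count and sampling interval")
  }
  sa <- .datasetSegments(a)$segments
  sb <- .datasetSegments(b)$segments
  n <- max(length(sa), length(sb))
  out <- list()
  for (i in seq_len(n)) {
    if (i <= length(sa)) out <- c(out, sa[i])
    if (i <= length(sb)) out <- c(out, sb[i])
  }
  out
}
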