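#' @include connectome.R preprocess.R
NULL

.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a structural connectome from a delimited table
#'
#' Expects a square numeric table (TSV by default, CSV for `.csv` paths),
#' optionally with a first header row of region labels. Asymmetry beyond
#' 1e-10 or a non-square table is a parse error reporting the offending
#' entries.
#'
#' @param path file to read.
#' @param areasPath optional sidecar table (label, area mm^2) of per-region
#'   surface areas.
#' @return a [StructuralConnectome-class].
#' @export
readConnectome <- function(path, areasPath = NULL) {
  sep <- .sepFor(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- tryCatch(
    utils::read.table(path, header = hasHeader, sep = sep,
                      check.names = FALSE),
    error = function(e) stop("malformed connectome table '", path, "': ",
                             conditionMessage(e)))
  W <- as.matrix(tab)
  if (!is.numeric(W)) stop("connectome table contains non-numeric entries")
  if (nrow(W) != ncol(W)) {
    stop(sprintf("connectome table is not square: %d rows x %d columns",
                 nrow(W), ncol(W)))
  }
  d <- abs(W - t(W))
  if (max(d) > .SYM_TOL) {
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "connectome table asymmetric beyond %g at entry (%d, %d): %g vs %g",
      .SYM_TOL, ij[1], ij[2], W[ij[1], ij[2]], W[ij[2], ij[1]]))
  }
  labels <- if (hasHeader) colnames(W) else NULL
  conn <- structuralConnectome(W, regionLabels = labels)
  if (!is.null(areasPath)) {
    at <- utils::read.table(areasPath, header = FALSE, sep = .sepFor(areasPath),
                            col.names = c("label", "area"))
    idx <- match(regionLabels(conn), at$label)
    if (anyNA(idx)) stop("surface-area sidecar misses region(s): ",
                         paste(regionLabels(conn)[is.na(idx)], collapse = ", "))
    surfaceAreas(conn) <- at$area[idx]
  }
  conn
}

#' Write a structural connectome
#'
#' Region labels go in a header row; weights are written with full double
#' precision so a read/write round trip reproduces them within 1e-12.
#'
#' @param conn a [StructuralConnectome-class].
#' @param path destination (TSV, or CSV for `.csv` paths).
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  W <- conn@weights
  colnames(W) <- regionLabels(conn)
  utils::write.table(format(W, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = .sepFor(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a region x time series with its sampling interval
#'
#' Plain delimited table with a `# sampling_interval=<s>` comment line on
#' top; regions are rows.
#'
#' @param ts region x time matrix or [Trajectory-class] (transposed to
#'   regions x time).
#' @param path destination.
#' @param samplingInterval seconds per timepoint (taken from a Trajectory
#'   automatically).
#' @return `path`, invisibly.
#' @export
writeTimeseries <- function(ts, path, samplingInterval = 0.72) {
  if (is(ts, "Trajectory")) {
    samplingInterval <- ts@samplingInterval
    ts <- t(ts@states)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_interval=%.17g", samplingInterval), con)
  utils::write.table(format(ts, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = .sepFor(path), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region x time series written by [writeTimeseries()]
#'
#' @param path file to read.
#' @return list with `ts` (region x time matrix) and `samplingInterval`.
#' @export
readTimeseries <- function(path) {
  hdr <- readLines(path, n = 1L)
  si <- 0.72
  skip <- 0L
  if (startsWith(hdr, "#")) {
    m <- regmatches(hdr, regexec("sampling_interval=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2) si <- as.numeric(m[2])
    skip <- 1L
  }
  ts <- as.matrix(utils::read.table(path, header = FALSE, sep = .sepFor(path),
                                    skip = skip))
  dimnames(ts) <- NULL
  list(ts = ts, samplingInterval = si)
}

#' Read a dataset manifest
#'
#' A YAML file listing per-subject timeseries files plus shared metadata:
#' fields `subjects` (paths relative to the manifest), optional
#' `sampling_interval` and `segment_length`.
#'
#' @param path manifest file.
#' @return a [TimeseriesDataset-class].
#' @export
readDatasetManifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$subjects)) stop("manifest has no 'subjects' field")
  base <- dirname(path)
  reads <- lapply(file.path(base, man$subjects), readTimeseries)
  si <- unique(vapply(reads, `[[`, 1, "samplingInterval"))
  if (length(si) > 1) stop("subject files disagree on sampling interval")
  timeseriesDataset(lapply(reads, `[[`, "ts"),
                    samplingInterval = man$sampling_interval %||% si,
                    segmentLength = man$segment_length %||% 50L,
                    provenance = list(manifest = path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
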