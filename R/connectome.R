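#' @include AllGenerics.R
NULL

#' Construct a StructuralConnectome
#'
#' @param weights square numeric matrix of nonnegative symmetric weights
#'   (zero diagonal; small numerical asymmetry within 1e-10 is symmetrized).
#' @param regionLabels optional character vector of region names; defaults
#'   to `R1..Rn` or the matrix dimnames when present.
#' @param surfaceAreas optional positive per-region areas in mm^2.
#' @param normalized logical; set by [normalizeSpectral()], rarely by hand.
#' @return a [StructuralConnectome-class].
#' @export
structuralConnectome <- function(weights, regionLabels = NULL,
                                 surfaceAreas = numeric(0),
                                 normalized = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be square, got ",
         nrow(weights), "x", ncol(weights))
  }
  if (max(abs(weights - t(weights))) <= .SYM_TOL) {
    weights <- (weights + t(weights)) / 2   # remove round-off asymmetry
  }
  if (is.null(regionLabels)) {
    regionLabels <- if (!is.null(rownames(weights))) rownames(weights)
                    else paste0("R", seq_len(nrow(weights)))
  }
  dimnames(weights) <- NULL
  new("StructuralConnectome", weights = weights,
      regionLabels = as.character(regionLabels),
      surfaceAreas = as.numeric(surfaceAreas),
      normalized = isTRUE(normalized))
}

#' @describeIn structuralConnectome spec of an edge-relocation perturbation.
#' @param fraction proportion of edges to relocate, in [0, 1].
#' @param seed integer seed.
#' @export
perturbationSpec <- function(fraction, seed = 1L) {
  new("PerturbationSpec", fraction = as.numeric(fraction),
      seed = as.integer(seed))
}

#' @rdname nRegions
#' @export
setMethod("nRegions", "StructuralConnectome", function(x) nrow(x@weights))

#' @rdname scWeights
#' @export
setMethod("scWeights", "StructuralConnectome", function(x) x@weights)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "StructuralConnectome", function(x) x@regionLabels)

#' @rdname surfaceAreas
#' @export
setMethod("surfaceAreas", "StructuralConnectome", function(x) x@surfaceAreas)

#' @rdname surfaceAreas-set
#' @export
setReplaceMethod("surfaceAreas", "StructuralConnectome", function(x, value) {
  x@surfaceAreas <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "StructuralConnectome", function(x) x@normalized)

setMethod("show", "StructuralConnectome", function(object) {
  W <- object@weights
  ne <- sum(W[upper.tri(W)] > 0)
  cat(sprintf("StructuralConnectome: %d regions, %d edges%s\n",
              nRegions(object), ne,
              if (object@normalized) " (spectrally normalized)" else ""))
  lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  cat(sprintf("  largest eigenvalue: %.6g; density: %.3f\n",
              lam, ne / choose(nRegions(object), 2)))
  if (length(object@surfaceAreas)) {
    cat(sprintf("  surface areas: mean %.1f mm^2\n", mean(object@surfaceAreas)))
  }
  invisible(object)
})

#' @rdname normalizeSpectral
#' @export
setMethod("normalizeSpectral", "StructuralConnectome", function(conn) {
  W <- conn@weights
  lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  if (lam <= .SPEC_TOL) {
    stop("cannot normalize: weight matrix has no positive eigenvalue ",
         "(all-zero connectome?)")
  }
  conn@weights <- W / lam
  conn@normalized <- TRUE
  validObject(conn)
  conn
})

#' @rdname stabilityMargin
#' @export
setMethod("stabilityMargin", "StructuralConnectome", function(conn, k) {
  stopifnot(is.numeric(k), length(k) == 1)
  lam <- eigen(conn@weights, symmetric = TRUE, only.values = TRUE)$values
  max(k * lam - 1)
})

.perturbEdgesImpl <- function(conn, fraction) {
  W <- conn@weights
  n <- nrow(W)
  up <- which(upper.tri(W))
  edges <- up[W[up] > 0]
  holes <- up[W[up] == 0]
  nMove <- round(fraction * length(edges))
  if (nMove == 0) return(conn)
  if (nMove > length(holes)) {
    stop(sprintf(
      "cannot relocate %d edges: only %d empty node pairs available (max feasible fraction %.3f)",
      nMove, length(holes), length(holes) / length(edges)))
  }
  src <- if (length(edges) == 1) edges else sample(edges, nMove)
  dst <- if (length(holes) == 1) holes else sample(holes, nMove)
  W[dst] <- W[src]
  W[src] <- 0
  # mirror lower triangle
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  conn@weights <- W
  conn@normalized <- FALSE  # relocation changes the spectrum
  validObject(conn)
  conn
}

#' @rdname perturbEdges
#' @export
setMethod("perturbEdges", signature("StructuralConnectome", "PerturbationSpec"),
  function(conn, spec, ...) {
    withr::with_seed(spec@seed, .perturbEdgesImpl(conn, spec@fraction))
  })

#' @rdname perturbEdges
#' @export
setMethod("perturbEdges", signature("StructuralConnectome", "numeric"),
  function(conn, spec, seed = NULL, ...) {
    if (spec < 0 || spec > 1) stop("fraction must be in [0, 1]")
    if (is.null(seed)) .perturbEdgesImpl(conn, spec)
    else withr::with_seed(as.integer(seed), .perturbEdgesImpl(conn, spec))
  })

#' Synthesize a random structural connectome
#'
#' Generates a symmetric, nonnegative, weighted random graph emulating a
#' cortical parcellation. With `bilateral = TRUE` the network has two
#' mirrored hemispheres of `nRegions/2` regions each: identical
#' within-hemisphere blocks and a sparser cross-hemisphere block whose
#' homotopic (region-to-same-region) connections are always present.
#' Weights are log-normal, mimicking the heavy tail of tractography fiber
#' counts. The result is returned unnormalized; apply
#' [normalizeSpectral()] before simulating.
#'
#' @param nRegions number of regions (even if `bilateral`).
#' @param density fraction of node pairs connected, in (0, 1].
#' @param seed integer seed.
#' @param bilateral mirror the network across two hemispheres.
#' @param surfaceAreas optionally attach per-region areas; `TRUE` draws
#'   areas around the cortical mean parcel area of 858 mm^2.
#' @return an unnormalized [StructuralConnectome-class].
#' @examples
#' conn <- synthConnectome(66, density = 0.3, seed = 1, bilateral = TRUE)
#' nRegions(conn)
#' @export
synthConnectome <- function(nRegions, density = 0.3, seed = 1L,
                            bilateral = FALSE, surfaceAreas = FALSE) {
  if (nRegions < 2) stop("nRegions must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (bilateral && nRegions %% 2 != 0) {
    stop("nRegions must be even for a bilateral connectome")
  }
  withr::with_seed(as.integer(seed), {
    rw <- function(m) matrix(stats::rlnorm(m * m, 0, 1), m, m)
    if (bilateral) {
      h <- nRegions %/% 2
      B <- rw(h); B[lower.tri(B)] <- t(B)[lower.tri(B)]; diag(B) <- 0
      keep <- matrix(stats::runif(h * h) < density, h, h)
      keep[lower.tri(keep)] <- t(keep)[lower.tri(keep)]
      B <- B * keep
      C <- rw(h)
      keepC <- matrix(stats::runif(h * h) < density / 2, h, h)
      diag(keepC) <- TRUE               # homotopic connections
      C <- C * keepC
      C <- (C + t(C)) / 2               # symmetric cross-block
      W <- rbind(cbind(B, C), cbind(C, B))
      labels <- c(paste0("L", seq_len(h)), paste0("R", seq_len(h)))
    } else {
      W <- rw(nRegions)
      W[lower.tri(W)] <- t(W)[lower.tri(W)]
      keep <- matrix(stats::runif(nRegions^2) < density, nRegions, nRegions)
      keep[lower.tri(keep)] <- t(keep)[lower.tri(keep)]
      W <- W * keep
      diag(W) <- 0
      labels <- paste0("R", seq_len(nRegions))
    }
    diag(W) <- 0
    areas <- if (isTRUE(surfaceAreas)) {
      stats::rlnorm(nRegions, log(858), 0.4)
    } else numeric(0)
    structuralConnectome(W, regionLabels = labels, surfaceAreas = areas)
  })
}

#' Build a ladder of increasingly perturbed connectomes
#'
#' One connectome per perturbation fraction, nested along a common seeded
#' stream: a single random ordering of the original edges and of the empty
#' node pairs is drawn once, and the rung at fraction f relocates the
#' first `round(f * nEdges)` edges onto the first empty slots. Each rung
#' is therefore marginally an edge relocation at its fraction, rungs share
#' their relocations, and the Frobenius distance from the original is
#' non-decreasing along the ladder by construction. The first entry
#' (fraction 0) is the original.
#'
#' @param conn the original [StructuralConnectome-class].
#' @param fractions ascending fractions starting at 0.
#' @param seed integer seed for the shared stream.
#' @return named list of [StructuralConnectome-class], names = fractions.
#' @export
perturbationLadder <- function(conn, fractions, seed = 1L) {
  if (is.unsorted(fractions, strictly = FALSE)) {
    stop("fractions must be sorted ascending")
  }
  if (fractions[1] != 0) stop("fractions must start at 0")
  W <- conn@weights
  up <- which(upper.tri(W))
  edges <- up[W[up] > 0]
  holes <- up[W[up] == 0]
  nMax <- round(max(fractions) * length(edges))
  if (nMax > length(holes)) {
    stop(sprintf(
      "cannot relocate %d edges: only %d empty node pairs available (max feasible fraction %.3f)",
      nMax, length(holes), length(holes) / length(edges)))
  }
  ord <- withr::with_seed(as.integer(seed), {
    list(src = sample(edges), dst = sample(holes))
  })
  out <- lapply(fractions, function(f) {
    nMove <- round(f * length(edges))
    if (nMove == 0) return(conn)
    Wp <- W
    Wp[ord$dst[seq_len(nMove)]] <- Wp[ord$src[seq_len(nMove)]]
    Wp[ord$src[seq_len(nMove)]] <- 0
    Wp[lower.tri(Wp)] <- t(Wp)[lower.tri(Wp)]
    pc <- conn
    pc@weights <- Wp
    pc@normalized <- FALSE
    validObject(pc)
    pc
  })
  names(out) <- as.character(fractions)
  out
}
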