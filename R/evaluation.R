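#' @include estimator.R
NULL

#' Coefficient of determination across regions
#'
#' \eqn{r^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2},
#' computed over the region axis at one timepoint. Unlike a squared
#' correlation this can be negative: a model whose prediction is farther
#' from the observation than the observation's own mean scores below zero.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @return a single numeric value <= 1.
#' @examples
#' rSquared(c(1, 2, 4), c(1, 2, 3))  # 0.5
#' @export
rSquared <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2) {
    stop("pred and obs must have equal length >= 2")
  }
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) stop("observations have zero variance")
  1 - sum((obs - pred)^2) / tss
}

#' Score predictions per horizon over a dataset
#'
#' For every segment and every anchor timepoint past the warmup, estimates
#' the state (or takes the observation itself as the state, the "null
#' initial condition"), propagates the system forward, and scores the
#' prediction against the observed future with [rSquared()] and mean
#' squared error at each horizon. With `sigma > 0` the forward simulation
#' is stochastic and scores are averaged over `nRealizations` noise draws.
#'
#' Aggregation: `"group"` pools the (region x subject) prediction errors
#' of the whole batch at a timepoint before scoring, giving one trial per
#' timepoint with much smaller variance; `"individual"` scores each
#' segment separately.
#'
#' @param est a [TrainedEstimator-class]; may be `NULL` when
#'   `icSource = "observation"` and `system` is given.
#' @param dataset a [TimeseriesDataset-class] or list of segments.
#' @param horizons integer horizons (sampled steps) to score.
#' @param sigma evaluation noise amplitude.
#' @param nRealizations noise draws averaged per trial when `sigma > 0`.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param aggregation "group" or "individual".
#' @param icSource "estimator" (the trained network's output) or
#'   "observation" (the measurement at the anchor time, the null).
#' @param system required when `est` is `NULL`.
#' @param warmup anchor timepoints start here; defaults to the estimator's
#'   training warmup (or 10 without an estimator).
#' @return a [HorizonScores-class].
#' @export
horizonScores <- function(est = NULL, dataset, horizons = 1:4, sigma = 0,
                          nRealizations = 10L, seed = NULL,
                          aggregation = c("group", "individual"),
                          icSource = c("estimator", "observation"),
                          system = NULL, warmup = NULL) {
  aggregation <- match.arg(aggregation)
  icSource <- match.arg(icSource)
  if (icSource == "estimator" && is.null(est)) {
    stop("icSource = 'estimator' needs a trained estimator")
  }
  if (is.null(system)) system <- est@system
  if (!is.null(est)) .checkSystem(est, system)
  if (is.null(warmup)) warmup <- if (!is.null(est)) est@config@warmup else 10L
  dt <- if (!is.null(est)) est@samplingInterval
        else if (is(dataset, "TimeseriesDataset")) dataset@samplingInterval
        else 0.72
  ds <- if (is(dataset, "TimeseriesDataset")) .datasetSegments(dataset)
        else list(segments = dataset, subject = seq_along(dataset))
  segs <- ds$segments
  if (!length(segs)) stop("dataset has no segments")
  n <- nrow(segs[[1]]); L <- ncol(segs[[1]]); B <- length(segs)
  maxH <- max(horizons)
  if (warmup + maxH > L) stop("horizons do not fit the segment past warmup")
  evalT <- seq.int(warmup, L - maxH)
  nT <- length(evalT)
  X <- array(0, c(n, L, B))
  for (b in seq_len(B)) X[, , b] <- segs[[b]]
  run <- function() {
    IC <- if (icSource == "estimator") {
      fw <- .lstmForward(est@weights, X, needCache = FALSE)
      fw$Y
    } else X
    M <- nT * B
    ICmat <- matrix(IC[, evalT, ], n, M)     # columns: t fastest, then segment
    E <- propagator(system, dt)
    det <- vector("list", maxH)
    det[[1]] <- E %*% ICmat
    if (maxH > 1) for (h in 2:maxH) det[[h]] <- E %*% det[[h - 1]]
    obs <- lapply(seq_len(maxH), function(h) matrix(X[, evalT + h, ], n, M))
    R <- if (sigma > 0) nRealizations else 1L
    noise <- .noiseSampler(system, dt, sigma)
    r2sum <- matrix(0, M0 <- if (aggregation == "group") nT else M,
                    length(horizons))
    msesum <- matrix(0, nrow(r2sum), length(horizons))
    groupIdx <- if (aggregation == "group") {
      lapply(seq_len(nT), function(ti) ti + nT * (0:(B - 1)))
    } else NULL
    for (r in seq_len(R)) {
      eta <- matrix(0, n, M)
      hi <- 0L
      for (h in seq_len(maxH)) {
        eta <- E %*% eta + noise(M)
        if (!h %in% horizons) next
        hi <- hi + 1L
        P <- det[[h]] + eta
        Ob <- obs[[h]]
        if (aggregation == "individual") {
          rss <- colSums((Ob - P)^2)
          cm <- colMeans(Ob)
          tss <- colSums((Ob - rep(cm, each = n))^2)
          r2sum[, hi] <- r2sum[, hi] + (1 - rss / tss)
          msesum[, hi] <- msesum[, hi] + rss / n
        } else {
          for (ti in seq_len(nT)) {
            jj <- groupIdx[[ti]]
            ov <- as.numeric(Ob[, jj]); pv <- as.numeric(P[, jj])
            rss <- sum((ov - pv)^2)
            tss <- sum((ov - mean(ov))^2)
            r2sum[ti, hi] <- r2sum[ti, hi] + (1 - rss / tss)
            msesum[ti, hi] <- msesum[ti, hi] + rss / length(ov)
          }
        }
      }
    }
    r2 <- r2sum / R; mse <- msesum / R
    if (aggregation == "group") {
      df <- data.frame(
        trial = rep(seq_len(nT), times = length(horizons)),
        subject = NA_integer_,
        tIndex = rep(evalT, times = length(horizons)),
        horizon = rep(horizons, each = nT),
        r2 = as.numeric(r2), mse = as.numeric(mse))
    } else {
      df <- data.frame(
        trial = rep(seq_len(M), times = length(horizons)),
        subject = rep(rep(ds$subject, each = nT), times = length(horizons)),
        tIndex = rep(rep(evalT, times = B), times = length(horizons)),
        horizon = rep(horizons, each = M),
        r2 = as.numeric(r2), mse = as.numeric(mse))
    }
    new("HorizonScores", scores = df, aggregation = aggregation,
        nTrials = as.integer(nrow(r2)))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

setMethod("show", "HorizonScores", function(object) {
  agg <- stats::aggregate(r2 ~ horizon, object@scores, mean)
  cat(sprintf("HorizonScores (%s aggregation, %d trials/horizon)\n",
              object@aggregation, object@nTrials))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  horizon %d: mean r2 = %.4f\n", agg$horizon[i], agg$r2[i]))
  }
  invisible(object)
})

#' Mean scores per horizon
#' @param scores a [HorizonScores-class].
#' @return data.frame with columns horizon, mean_r2, mean_mse.
#' @export
meanScores <- function(scores) {
  df <- scores@scores
  out <- stats::aggregate(cbind(r2, mse) ~ horizon, df, mean)
  names(out) <- c("horizon", "mean_r2", "mean_mse")
  out
}

#' Structural-sensitivity slope
#'
#' Least-squares slope of mean accuracy against the connectome
#' perturbation fraction. A more negative slope means the model's accuracy
#' depends more strongly on having the correct structural network; cells
#' are ranked by slope magnitude.
#'
#' @param fractions numeric perturbation fractions (>= 2 distinct values).
#' @param meanR2 mean r-squared at each fraction.
#' @return the signed slope (accuracy units per unit fraction).
#' @examples
#' sensitivitySlope(c(0, 0.5, 1), c(0.6, 0.4, 0.2))  # -0.4
#' @export
sensitivitySlope <- function(fractions, meanR2) {
  if (length(fractions) != length(meanR2) ||
      length(unique(fractions)) < 2) {
    stop("need >= 2 distinct fractions with matching scores")
  }
  unname(stats::coef(stats::lm(meanR2 ~ fractions))[2])
}

#' Train the estimator grid for a sweep
#'
#' One estimator per (coupling, perturbation fraction) cell: the
#' connectome ladder supplies the perturbed networks, and each cell's
#' system is the noiseless FRM with that coupling on that network.
#' Training seeds are derived from `seed` per cell so the grid is
#' reproducible.
#'
#' @param dataset training data ([TimeseriesDataset-class]).
#' @param connectome the original (normalized) [StructuralConnectome-class].
#' @param kValues global coupling values.
#' @param fractions perturbation fractions (ascending, starting at 0).
#' @param config an [EstimatorConfig-class] shared across cells.
#' @param seed integer; cell seeds are `seed + cell index`.
#' @return list with `entries` (list of k, fraction, estimator), `kValues`,
#'   `fractions`, and the connectome `ladder`.
#' @export
trainEstimatorGrid <- function(dataset, connectome, kValues, fractions,
                               config = estimatorConfig(), seed = 1L) {
  ladder <- perturbationLadder(connectome, fractions, seed = seed)
  entries <- list()
  cell <- 0L
  for (f in fractions) {
    for (k in kValues) {
      cell <- cell + 1L
      cfg <- config
      cfg@seed <- as.integer(seed + cell)
      sys <- frmModel(ladder[[as.character(f)]], k = k, sigma = 0)
      entries[[cell]] <- list(
        k = k, fraction = f,
        estimator = trainEstimator(dataset, sys, cfg))
    }
  }
  list(entries = entries, kValues = kValues, fractions = fractions,
       ladder = ladder)
}

#' Sweep accuracy over coupling, noise and structural perturbation
#'
#' Fills the (k, sigma, fraction) grid with mean accuracy at the requested
#' horizons via [horizonScores()], computes the structural-sensitivity
#' slope per (k, sigma) at the selection horizon, and reports the cell of
#' maximum slope magnitude: the parameterization at which the model is
#' most sensitive to having the correct structural network, which is the
#' selection criterion when the true noise level is unknown.
#'
#' @param grid estimator grid from [trainEstimatorGrid()].
#' @param dataset evaluation data (held out from training).
#' @param sigmaValues evaluation noise amplitudes.
#' @param horizons horizons to score.
#' @param selectionHorizon horizon at which slopes and the argmax are
#'   taken (default 4, where model differentiation peaks).
#' @param nRealizations noise draws per trial.
#' @param seed integer seed for the whole sweep.
#' @param aggregation "group" or "individual".
#' @return a [SweepResult-class].
#' @export
parameterSweep <- function(grid, dataset, sigmaValues, horizons = 1:4,
                           selectionHorizon = 4L, nRealizations = 10L,
                           seed = 1L, aggregation = "group") {
  kValues <- grid$kValues; fractions <- grid$fractions
  have <- vapply(grid$entries, function(e) paste(e$k, e$fraction), "")
  need <- as.vector(outer(kValues, fractions, paste))
  if (!all(need %in% have)) {
    stop("missing estimator(s) for cell(s): ",
         paste(setdiff(need, have), collapse = "; "))
  }
  if (!selectionHorizon %in% horizons) horizons <- sort(c(horizons, selectionHorizon))
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (e in grid$entries) {
      for (sg in sigmaValues) {
        hs <- horizonScores(e$estimator, dataset, horizons = horizons,
                            sigma = sg, nRealizations = nRealizations,
                            seed = NULL, aggregation = aggregation)
        ms <- meanScores(hs)
        rows[[length(rows) + 1L]] <- data.frame(
          k = e$k, sigma = sg, fraction = e$fraction,
          horizon = ms$horizon, mean_r2 = ms$mean_r2, mean_mse = ms$mean_mse)
      }
    }
  })
  scores <- do.call(rbind, rows)
  slopes <- do.call(rbind, lapply(split(
    scores[scores$horizon == selectionHorizon, ],
    list(scores$k[scores$horizon == selectionHorizon],
         scores$sigma[scores$horizon == selectionHorizon]), drop = TRUE),
    function(d) data.frame(k = d$k[1], sigma = d$sigma[1],
                           horizon = selectionHorizon,
                           slope = sensitivitySlope(d$fraction, d$mean_r2))))
  rownames(slopes) <- NULL
  best <- slopes[which.max(abs(slopes$slope)), ]
  new("SweepResult", scores = scores, slopes = slopes,
      argmax = list(k = best$k, sigma = best$sigma, slope = best$slope,
                    horizon = selectionHorizon, criterion = "max |slope|"),
      axes = list(k = kValues, sigma = sigmaValues, fraction = fractions,
                  horizon = horizons))
}

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over axes:\n")
  for (nm in names(object@axes)) {
    cat("  ", nm, ": ", paste(object@axes[[nm]], collapse = ", "), "\n", sep = "")
  }
  if (length(object@argmax)) {
    am <- object@argmax
    cat("  argmax (", am$criterion %||% "", "): ",
        paste(names(am)[1:2], unlist(am[1:2]), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(object)
})

#' Functional connectivity matrix
#'
#' Pearson correlation of every region pair over time: symmetric with unit
#' diagonal.
#'
#' @param x a [Trajectory-class], or a region x time matrix.
#' @return n x n correlation matrix.
#' @export
fcMatrix <- function(x) {
  ts <- if (is(x, "Trajectory")) x@states else t(as.matrix(x))
  if (nrow(ts) < 3) stop("need at least 3 timepoints for FC")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ", paste(which(sds == 0), collapse = ", "))
  }
  stats::cor(ts)
}

#' Similarity of two FC matrices
#'
#' Pearson correlation of the upper triangles (diagonal excluded).
#'
#' @param fcA,fcB n x n FC matrices.
#' @return a single correlation.
#' @export
fcSimilarity <- function(fcA, fcB) {
  if (!all(dim(fcA) == dim(fcB))) stop("FC matrices differ in size")
  ut <- upper.tri(fcA)
  stats::cor(fcA[ut], fcB[ut])
}

.referenceFC <- function(reference) {
  if (is(reference, "TimeseriesDataset")) {
    fcs <- lapply(reference@subjects, fcMatrix)
    Reduce(`+`, fcs) / length(fcs)
  } else {
    m <- as.matrix(reference)
    if (nrow(m) == ncol(m) && max(abs(m - t(m))) < 1e-8 &&
        all(abs(diag(m) - 1) < 1e-8)) m else fcMatrix(m)
  }
}

#' Long-term FC parameterization of the FRM
#'
#' The traditional model-fitting route: simulate each (k, sigma) cell for
#' a long window, correlate the simulation's FC with the reference FC, and
#' select the cell of maximum similarity. Unstable cells (numerical
#' overflow) are flagged rather than fatal. Note that for this linear
#' model the stationary FC is invariant to a uniform sigma, so the sigma
#' axis differentiates cells only through finite-sample fluctuation.
#'
#' @param connectome normalized [StructuralConnectome-class].
#' @param reference a [TimeseriesDataset-class], region x time matrix, or
#'   precomputed FC matrix.
#' @param kValues,sigmaValues grid axes.
#' @param durationSteps sampled steps per simulation (>= 100; the default
#'   1667 steps of 0.72 s is a 20-minute window).
#' @param samplingInterval seconds per step.
#' @param burnIn discarded initial steps.
#' @param seed integer seed.
#' @return a [SweepResult-class] with `fc_similarity` scores.
#' @export
longTermParameterization <- function(connectome, reference, kValues,
                                     sigmaValues, durationSteps = 1667L,
                                     samplingInterval = 0.72, burnIn = 100L,
                                     seed = 1L) {
  if (durationSteps < 100) stop("durationSteps must be >= 100")
  refFC <- .referenceFC(reference)
  n <- nRegions(connectome)
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (k in kValues) {
      for (sg in sigmaValues) {
        sim <- tryCatch({
          tr <- simulateTrajectory(frmModel(connectome, k, sg),
                                   x0 = stats::rnorm(n),
                                   nSteps = burnIn + durationSteps,
                                   samplingInterval = samplingInterval)
          fc <- fcMatrix(tr@states[-seq_len(burnIn + 1L), ] |> t())
          list(sim = fcSimilarity(fc, refFC), unstable = FALSE)
        }, error = function(e) list(sim = NA_real_, unstable = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, sigma = sg, fc_similarity = sim$sim, unstable = sim$unstable)
      }
    }
  })
  scores <- do.call(rbind, rows)
  ok <- which(!scores$unstable)
  best <- scores[ok[which.max(scores$fc_similarity[ok])], ]
  new("SweepResult", scores = scores, slopes = data.frame(),
      argmax = list(k = best$k, sigma = best$sigma,
                    fc_similarity = best$fc_similarity,
                    criterion = "max FC similarity"),
      axes = list(k = kValues, sigma = sigmaValues))
}

#' Region of Predictability
#'
#' Compares estimator-derived initial conditions against null initial
#' conditions (the measurement at the anchor time) over the first few
#' seconds: per horizon within the window, a paired two-sided Wilcoxon
#' signed-rank test on the trial-wise accuracy, declared significant when
#' p < alpha and the estimator's mean accuracy is higher.
#'
#' @param nodeScores,nullScores [HorizonScores-class] with individual
#'   aggregation and identical trial structure (use the same seed so noise
#'   realizations pair up).
#' @param windowSeconds length of the window (default 3.6 s = 5 horizons
#'   at 0.72 s).
#' @param samplingInterval seconds per horizon step.
#' @param alpha significance level per horizon.
#' @return list with `table` (per-horizon means and p-values),
#'   `windowMeanNode`, `windowMeanNull`, and `significantHorizons`.
#' @export
regionOfPredictability <- function(nodeScores, nullScores,
                                   windowSeconds = 3.6,
                                   samplingInterval = 0.72, alpha = 0.05) {
  wH <- max(1L, floor(round(windowSeconds / samplingInterval, 6)))
  a <- nodeScores@scores; b <- nullScores@scores
  horizons <- intersect(unique(a$horizon), unique(b$horizon))
  horizons <- sort(horizons[horizons <= wH])
  if (length(horizons) < 1 || !all(seq_len(wH) %in% horizons)) {
    stop("score sets must cover every horizon in the ", windowSeconds,
         " s window (", wH, " horizons)")
  }
  rows <- lapply(horizons, function(h) {
    xa <- a$r2[a$horizon == h][order(a$trial[a$horizon == h])]
    xb <- b$r2[b$horizon == h][order(b$trial[b$horizon == h])]
    if (length(xa) != length(xb)) {
      stop("trial counts differ at horizon ", h, " (", length(xa), " vs ",
           length(xb), ")")
    }
    d <- xa - xb
    p <- if (all(abs(d) < 1e-15)) 1 else
      stats::wilcox.test(xa, xb, paired = TRUE, exact = FALSE)$p.value
    data.frame(horizon = h, meanNode = mean(xa), meanNull = mean(xb),
               p = p, significant = (p < alpha) && (mean(d) > 0))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       windowMeanNode = mean(tab$meanNode),
       windowMeanNull = mean(tab$meanNull),
       significantHorizons = tab$horizon[tab$significant])
}
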