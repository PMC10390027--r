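test_that("the autoregressive null trains to the persistence optimum", {
  segs <- smoothSegments(nSeg = 10, n = 4, len = 30, rho = 0.95, seed = 3)
  est <- trainEstimator(segs, arModel(4),
                        quickConfig(hiddenSize = 32L, nEpochs = 150L,
                                    learningRate = 3e-3, patience = 20L),
                        samplingInterval = 0.72)
  # loss floor of the persistence forecast on this data
  floorLoss <- mean(vapply(segs, function(s) {
    mean((s[, 6:30] - s[, 5:29])^2)
  }, 1))
  final <- est@lossCurve[length(est@lossCurve)]
  expect_lt(final, 1.5 * floorLoss)
  # with identity propagator the output tracks the current observation
  prefix <- segs[[1]][, 1:20]
  ic <- estimateIC(est, prefix)
  expect_gt(cor(ic, prefix[, 20]), 0.9)
})

test_that("training and inference are deterministic under a seed", {
  segs <- smoothSegments(nSeg = 4, n = 3, len = 20, seed = 9)
  cfg <- quickConfig(nEpochs = 6L)
  a <- trainEstimator(segs, arModel(3), cfg, samplingInterval = 0.72)
  b <- trainEstimator(segs, arModel(3), cfg, samplingInterval = 0.72)
  expect_identical(a@lossCurve, b@lossCurve)
  expect_identical(estimateIC(a, segs[[1]][, 1:10]),
                   estimateIC(b, segs[[1]][, 1:10]))
  expect_error(estimateIC(a, matrix(numeric(0), 3, 0)), "t >= 1")
})

test_that("horizon-1 prediction is the one-step propagation of the estimate", {
  conn <- tinyConn(6, seed = 2)
  sys <- frmModel(conn, 0.9, 0)
  segs <- smoothSegments(nSeg = 6, n = 6, len = 25, seed = 4)
  est <- trainEstimator(segs, sys, quickConfig(nEpochs = 10L),
                        samplingInterval = 0.72)
  seg <- segs[[1]]
  ic <- estimateIC(est, seg[, 1:12])
  Phi <- propagator(sys, 0.72)
  pred <- predictHorizon(est, seg, 12, 3, sigma = 0)
  expect_equal(pred[1, ], as.numeric(Phi %*% ic), tolerance = 1e-12)

  # the AR null continues its estimate unchanged at every horizon
  estAR <- trainEstimator(segs, arModel(6), quickConfig(nEpochs = 5L),
                          samplingInterval = 0.72)
  icAR <- estimateIC(estAR, seg[, 1:12])
  predAR <- predictHorizon(estAR, seg, 12, 5, sigma = 0)
  for (h in 1:5) expect_equal(predAR[h, ], icAR, tolerance = 1e-12)

  # stochastic evaluation is reproducible under a seed
  p1 <- predictHorizon(est, seg, 12, 4, sigma = 0.3, seed = 8)
  p2 <- predictHorizon(est, seg, 12, 4, sigma = 0.3, seed = 8)
  expect_identical(p1, p2)

  expect_error(predictHorizon(est, seg, 2, 3), "warmup")
  expect_error(predictHorizon(est, seg, 12, 20), "past the segment")
})

test_that("spiral estimates sharpen as the prefix grows", {
  ds <- makeSpiralDataset(nSequences = 70, nTimepoints = 40,
                          noiseSd = 0.1, samplingInterval = 0.1, seed = 6)
  trainObs <- ds@observations[1:40]
  testIdx <- 41:70
  cfg <- estimatorConfig(hiddenSize = 32L, nEpochs = 50L, warmup = 2L,
                         seed = 1L)
  est <- trainEstimator(trainObs, spiralModel(ds@A), cfg,
                        samplingInterval = 0.1)
  distAt <- function(len) {
    mean(vapply(testIdx, function(i) {
      ic <- estimateIC(est, ds@observations[[i]][, 1:len, drop = FALSE])
      sqrt(sum((ic - ds@states[[i]][, len])^2))
    }, 1))
  }
  expect_lt(distAt(15), distAt(1))
})

test_that("the inference null samples a non-degenerate rollout", {
  segs <- smoothSegments(nSeg = 8, n = 3, len = 25, seed = 10)
  cfg <- quickConfig(nEpochs = 30L, distributional = TRUE)
  est <- trainEstimator(segs, arModel(3), cfg, samplingInterval = 0.72)
  prefix <- segs[[1]][, 1:10]

  expect_identical(dim(inferenceRollout(est, prefix, 0)), c(0L, 3L))
  r1 <- inferenceRollout(est, prefix, 5, seed = 1)
  r2 <- inferenceRollout(est, prefix, 5, seed = 2)
  expect_false(isTRUE(all.equal(r1, r2)))
  expect_identical(inferenceRollout(est, prefix, 5, seed = 3),
                   inferenceRollout(est, prefix, 5, seed = 3))

  rolls <- vapply(1:20, function(s) inferenceRollout(est, prefix, 4, seed = s),
                  matrix(0, 4, 3))
  stepVar <- apply(rolls, c(1, 2), var)
  expect_true(all(stepVar > 0))

  point <- trainEstimator(segs, arModel(3), quickConfig(nEpochs = 3L),
                          samplingInterval = 0.72)
  expect_error(inferenceRollout(point, prefix, 3), "distributional")
})
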