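test_that("the coefficient of determination behaves like one", {
  obs <- c(1, 2, 3)
  expect_equal(rSquared(obs, obs), 1)
  expect_equal(rSquared(rep(mean(obs), 3), obs), 0)
  expect_equal(rSquared(c(1, 2, 4), obs), 0.5)       # 1 - 1/2
  expect_lt(rSquared(c(10, -3, 7), obs), 0)          # worse than the mean
  expect_error(rSquared(1:3, c(2, 2, 2)), "zero variance")
  expect_error(rSquared(1:3, 1:4), "equal length")
})

test_that("sensitivity slope is the least-squares slope over fractions", {
  expect_equal(sensitivitySlope(c(0, 0.5, 1), c(0.6, 0.4, 0.2)), -0.4,
               tolerance = 1e-12)
  expect_equal(sensitivitySlope(c(0, 0.3, 0.6), rep(0.5, 3)), 0,
               tolerance = 1e-12)
  # order invariance
  expect_equal(sensitivitySlope(c(1, 0, 0.5), c(0.2, 0.6, 0.4)), -0.4,
               tolerance = 1e-12)
  expect_error(sensitivitySlope(0, 0.5), "distinct fractions")
})

test_that("functional connectivity is a correlation structure", {
  set.seed(1)
  ts <- matrix(rnorm(3 * 200), 3, 200)
  ts[2, ] <- ts[1, ]                 # perfectly coupled pair
  fc <- fcMatrix(ts)
  expect_equal(diag(fc), rep(1, 3))
  expect_equal(fc, t(fc))
  expect_equal(fc[1, 2], 1)
  expect_equal(fcSimilarity(fc, fc), 1)
  expect_error(fcMatrix(rbind(rnorm(50), rep(1, 50))), "zero-variance")

  # uncoupled regions decorrelate over long windows (k = 0 network)
  conn <- tinyConn(8, seed = 2)
  tr <- simulateTrajectory(frmModel(conn, 0, 0.3), rnorm(8), 3000, seed = 3)
  fc0 <- fcMatrix(tr)
  expect_lt(max(abs(fc0[upper.tri(fc0)])), 0.12)
})

test_that("horizon scoring is deterministic and refuses mismatched systems", {
  conn <- tinyConn(5, seed = 3)
  ds <- makeSurrogateBold(conn, 0.9, 0.3, nSubjects = 2, nTimepoints = 150,
                          seed = 4)
  sys <- frmModel(conn, 0.9, 0)
  a <- horizonScores(NULL, ds, horizons = 1:4, sigma = 0.3, seed = 5,
                     icSource = "observation", system = sys,
                     nRealizations = 3)
  b <- horizonScores(NULL, ds, horizons = 1:4, sigma = 0.3, seed = 5,
                     icSource = "observation", system = sys,
                     nRealizations = 3)
  expect_identical(a@scores, b@scores)
  expect_identical(a@aggregation, "group")
  # 150 timepoints -> 3 segments of 50; group trials = timepoints only
  expect_identical(a@nTrials, length(unique(a@scores$tIndex)))

  ind <- horizonScores(NULL, ds, horizons = 1:2, sigma = 0,
                       icSource = "observation", system = sys)
  expect_identical(ind@aggregation[1], "group")
  ind2 <- horizonScores(NULL, ds, horizons = 1:2, sigma = 0,
                        aggregation = "individual",
                        icSource = "observation", system = sys)
  expect_identical(ind2@nTrials, 6L * ind@nTrials)  # 2 subjects x 3 segments

  segs <- smoothSegments(nSeg = 4, n = 5, len = 30, seed = 6)
  est <- trainEstimator(segs, sys, quickConfig(nEpochs = 3L),
                        samplingInterval = 0.72)
  expect_error(horizonScores(est, ds, system = frmModel(conn, 0.45, 0)),
               "fingerprint")
})

test_that("group pooling is a steadier summary than individual scoring", {
  conn <- tinyConn(8, seed = 7)
  ds <- makeSurrogateBold(conn, 0.9, 0.3, nSubjects = 4, nTimepoints = 200,
                          seed = 8)
  sys <- frmModel(conn, 0.9, 0)
  summaries <- vapply(1:20, function(s) {
    g <- horizonScores(NULL, ds, horizons = 4, sigma = 0.3, seed = s,
                       nRealizations = 1, icSource = "observation",
                       system = sys, aggregation = "group")
    i <- horizonScores(NULL, ds, horizons = 4, sigma = 0.3, seed = s,
                       nRealizations = 1, icSource = "observation",
                       system = sys, aggregation = "individual")
    c(group = mean(g@scores$r2), individual = mean(i@scores$r2))
  }, c(group = 0, individual = 0))
  expect_lt(var(summaries["group", ]), var(summaries["individual", ]))
})

test_that("long-term FC fitting recovers the generating coupling", {
  conn <- tinyConn(12, seed = 9)
  ref <- makeSurrogateBold(conn, 0.9, 0.3, nSubjects = 2, nTimepoints = 400,
                           seed = 10, preprocess = FALSE)
  lt <- longTermParameterization(conn, ref, kValues = c(0, 0.45, 0.9),
                                 sigmaValues = 0.3, durationSteps = 800,
                                 seed = 11)
  expect_equal(lt@argmax$k, 0.9)
  sc <- lt@scores
  expect_lt(sc$fc_similarity[sc$k == 0], sc$fc_similarity[sc$k == 0.9])
  # argmax stable when the window doubles
  lt2 <- longTermParameterization(conn, ref, kValues = c(0, 0.45, 0.9),
                                  sigmaValues = 0.3, durationSteps = 1600,
                                  seed = 12)
  expect_equal(lt2@argmax$k, 0.9)
  expect_error(longTermParameterization(conn, ref, 0.9, 0.3,
                                        durationSteps = 50), ">= 100")
})

test_that("the Region of Predictability flags a uniform improvement", {
  mkScores <- function(r2, horizons = 1:5, nTrials = 100) {
    df <- expand.grid(trial = seq_len(nTrials), horizon = horizons)
    df$subject <- 1L; df$tIndex <- df$trial
    df$r2 <- r2[df$horizon] + rnorm(nrow(df), sd = 0.01)
    df$mse <- 1 - df$r2
    new("HorizonScores", scores = df, aggregation = "individual",
        nTrials = as.integer(nTrials))
  }
  withr::with_seed(13, {
    base <- mkScores(rep(0.5, 5))
    lifted <- mkScores(rep(0.7, 5))
    rp <- regionOfPredictability(lifted, base)
    expect_identical(rp$significantHorizons, 1:5)
    expect_gt(rp$windowMeanNode, rp$windowMeanNull)

    # identical scores: nothing significant
    same <- mkScores(rep(0.5, 5))
    rp0 <- regionOfPredictability(same, same)
    expect_length(rp0$significantHorizons, 0)

    # a 0.72 s window tests exactly one horizon
    rp1 <- regionOfPredictability(lifted, base, windowSeconds = 0.72)
    expect_identical(nrow(rp1$table), 1L)
  })
})
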