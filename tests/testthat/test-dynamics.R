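test_that("drift matches each model kind", {
  conn <- tinyConn(10, seed = 1)
  x <- rnorm(10)

  expect_equal(drift(arModel(10), x), rep(0, 10))
  expect_equal(drift(expDecayModel(2), c(2, -2)), c(-2, 2))

  # leading eigenvector identity: (k*lambda - 1) v with lambda = 1
  v <- eigen(scWeights(conn), symmetric = TRUE)$vectors[, 1]
  expect_equal(drift(frmModel(conn, 0.9), v), -0.1 * v, tolerance = 1e-9)

  expect_error(drift(arModel(10), c(1, 2)), "length")
})

test_that("noiseless simulation reproduces the matrix-exponential flow", {
  sys <- expDecayModel(1)
  tr <- simulateTrajectory(sys, 1, 1)
  expect_equal(states(tr)[2, ], exp(-0.72), tolerance = 1e-10)

  conn <- tinyConn(20, seed = 2)
  fsys <- frmModel(conn, 0.9, 0)
  x0 <- withr::with_seed(3, rnorm(20))
  tr <- simulateTrajectory(fsys, x0, 50)
  for (s in c(1, 10, 25, 50)) {
    expect_lt(max(abs(states(tr)[s + 1, ] -
                        closedFormLinear(fsys, x0, s * 0.72))), 1e-4)
  }

  # stability: norms decay toward zero
  nr <- apply(states(tr), 1, function(r) sqrt(sum(r^2)))
  expect_true(all(diff(nr) < 0))
  expect_lt(nr[51], 0.1 * nr[1])
})

test_that("plain Euler drift converges at first order", {
  sys <- expDecayModel(1)
  err <- function(m) {
    abs(states(simulateTrajectory(sys, 1, 1, substeps = m,
                                  scheme = "euler"))[2, ] - exp(-0.72))
  }
  ratio <- err(10) / err(20)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("noise increments respect the per-unit-time variance contract", {
  # drift-free system: increment variance per sampled step must be sigma^2 * dt
  sys <- arModel(4, sigma = 0.3)
  tr <- simulateTrajectory(sys, rep(0, 4), 2500, seed = 11)
  inc <- diff(states(tr))
  expect_equal(stats::var(as.numeric(inc)), 0.3^2 * 0.72, tolerance = 0.05)

  # ar is constant without noise
  trd <- simulateTrajectory(arModel(4), rnorm(4), 10, seed = 1)
  expect_equal(states(trd)[11, ], states(trd)[1, ])
})

test_that("simulation is seeded-deterministic and guards against overflow", {
  conn <- tinyConn(6, seed = 4)
  sys <- frmModel(conn, 0.9, 0.3)
  a <- simulateTrajectory(sys, rep(0, 6), 20, seed = 5)
  b <- simulateTrajectory(sys, rep(0, 6), 20, seed = 5)
  expect_identical(states(a), states(b))

  unstable <- frmModel(conn, 3, 0)   # margin +2: grows without bound
  expect_error(simulateTrajectory(unstable, rep(100, 6), 50),
               "overflow.*step", ignore.case = TRUE)
})

test_that("closed form matches a fine-step Runge-Kutta oracle on the spiral", {
  A <- matrix(c(-0.1, -2, 2, -0.1), 2, 2)
  sys <- spiralModel(A)
  x0 <- c(2, 0)
  expect_equal(closedFormLinear(sys, x0, 0), x0)

  # classical RK4 with 10000 steps as the independent oracle
  rk4 <- function(x, t, nStep = 10000L) {
    dt <- t / nStep
    for (i in seq_len(nStep)) {
      k1 <- A %*% x; k2 <- A %*% (x + dt / 2 * k1)
      k3 <- A %*% (x + dt / 2 * k2); k4 <- A %*% (x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    as.numeric(x)
  }
  expect_lt(max(abs(closedFormLinear(sys, x0, pi / 2) - rk4(x0, pi / 2))),
            1e-6)

  expect_equal(closedFormLinear(expDecayModel(3), c(2, 4, 8), log(2)),
               c(1, 2, 4), tolerance = 1e-12)
  expect_error(closedFormLinear(arModel(3), 1:3, 1), "unsupported")
})

test_that("surface-area noise scaling is linear through 858 mm^2", {
  expect_identical(areaScaledSigma(858), 0.35)
  expect_identical(areaScaledSigma(429), 0.175)
  expect_identical(areaScaledSigma(1716), 0.7)
  expect_error(areaScaledSigma(0), "positive")
  expect_error(areaScaledSigma(-10), "positive")
})
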