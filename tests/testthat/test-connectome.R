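test_that("spectral normalization rescales the leading eigenvalue to 1", {
  conn <- structuralConnectome(matrix(c(0, 2, 2, 0), 2))
  norm <- normalizeSpectral(conn)
  expect_equal(scWeights(norm), matrix(c(0, 1, 1, 0), 2))
  expect_true(isNormalized(norm))

  # idempotence on an already-normalized matrix
  expect_equal(scWeights(normalizeSpectral(norm)), scWeights(norm))

  # random 10-node matrix against the eigensolver oracle
  conn10 <- tinyConn(10, seed = 3, normalized = FALSE)
  lam <- max(eigen(scWeights(normalizeSpectral(conn10)),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(lam - 1), 1e-8)
})

test_that("normalization is scale-invariant and refuses a zero matrix", {
  conn <- tinyConn(8, seed = 5, normalized = FALSE)
  scaled <- structuralConnectome(scWeights(conn) * 37.5)
  expect_equal(scWeights(normalizeSpectral(scaled)),
               scWeights(normalizeSpectral(conn)), tolerance = 1e-12)
  zero <- structuralConnectome(matrix(0, 4, 4))
  expect_error(normalizeSpectral(zero), "positive eigenvalue")
})

test_that("connectome validity enforces symmetry, sign and diagonal", {
  expect_error(structuralConnectome(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  W <- matrix(c(0, -1, -1, 0), 2)
  expect_error(structuralConnectome(W), "nonnegative")
  W2 <- matrix(c(1, 1, 1, 0), 2)
  expect_error(structuralConnectome(W2), "diagonal")
})

test_that("edge perturbation preserves edge count, weights and symmetry", {
  conn <- tinyConn(10, seed = 2, density = 0.45, normalized = FALSE)
  W0 <- scWeights(conn)
  edgeCount <- function(W) sum(W[upper.tri(W)] > 0)
  weightSet <- function(W) sort(W[upper.tri(W)][W[upper.tri(W)] > 0])
  for (f in c(0.25, 0.5)) {
    p <- perturbEdges(conn, f, seed = 11)
    Wp <- scWeights(p)
    expect_identical(edgeCount(Wp), edgeCount(W0))
    expect_equal(weightSet(Wp), weightSet(W0))
    expect_lt(max(abs(Wp - t(Wp))), 1e-12)
    expect_true(all(diag(Wp) == 0))
    expect_false(isNormalized(p))
  }
})

test_that("edge perturbation is a seeded no-op at fraction 0 and deterministic", {
  conn <- tinyConn(10, seed = 2, normalized = FALSE)
  expect_identical(scWeights(perturbEdges(conn, 0, seed = 1)),
                   scWeights(conn))
  a <- perturbEdges(conn, 0.5, seed = 42)
  b <- perturbEdges(conn, perturbationSpec(0.5, seed = 42))
  expect_identical(scWeights(a), scWeights(b))
})

test_that("infeasible relocations name the feasible maximum", {
  dense <- structuralConnectome({
    W <- matrix(1, 6, 6); diag(W) <- 0; W[1, 2] <- W[2, 1] <- 0; W
  })
  # 14 edges, 1 hole: fraction 0.5 would need 7 holes
  expect_error(perturbEdges(dense, 0.5, seed = 1), "max feasible fraction")
})

test_that("perturbation distance grows with the fraction in expectation", {
  conn <- tinyConn(12, seed = 4, density = 0.35, normalized = FALSE)
  W0 <- scWeights(conn)
  frob <- function(f, seed) {
    norm(scWeights(perturbEdges(conn, f, seed = seed)) - W0, "F")
  }
  d1 <- mean(vapply(1:20, function(s) frob(0.2, s), 1))
  d2 <- mean(vapply(1:20, function(s) frob(0.6, s), 1))
  expect_gt(d2, d1)
})

test_that("synthetic bilateral connectome mirrors two hemisphere blocks", {
  conn <- synthConnectome(66, density = 0.3, seed = 9, bilateral = TRUE)
  W <- scWeights(conn)
  expect_identical(dim(W), c(66L, 66L))
  expect_identical(W[1:33, 1:33], W[34:66, 34:66])
  expect_lt(max(abs(W - t(W))), 1e-12)
  expect_identical(sum(startsWith(regionLabels(conn), "L")), 33L)

  full <- synthConnectome(6, density = 1, seed = 1)
  Wf <- scWeights(full)
  expect_true(all(Wf[upper.tri(Wf)] > 0))

  expect_identical(scWeights(synthConnectome(12, seed = 5)),
                   scWeights(synthConnectome(12, seed = 5)))
  expect_error(synthConnectome(1), "nRegions")
  expect_error(synthConnectome(7, bilateral = TRUE), "even")
})

test_that("stability margin equals k - 1 on a normalized connectome", {
  conn <- tinyConn(10, seed = 6)
  expect_equal(stabilityMargin(conn, 0.9), -0.1, tolerance = 1e-9)
  expect_equal(stabilityMargin(conn, 0), -1)
  expect_equal(stabilityMargin(conn, 1), 0, tolerance = 1e-9)
  for (k in c(0.2, 0.5, 0.99)) {
    expect_equal(stabilityMargin(conn, k), k - 1, tolerance = 1e-9)
  }
})

test_that("perturbation ladder starts at the original and drifts away monotonically", {
  conn <- tinyConn(12, seed = 8, normalized = FALSE)
  fr <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8)
  ladder <- perturbationLadder(conn, fr, seed = 3)
  expect_length(ladder, 6)
  expect_identical(scWeights(ladder[[1]]), scWeights(conn))
  ec <- vapply(ladder, function(c) sum(scWeights(c) > 0), 1)
  expect_true(all(ec == ec[1]))
  d <- vapply(ladder, function(c) norm(scWeights(c) - scWeights(conn), "F"), 1)
  expect_true(all(diff(d) >= 0))
  expect_error(perturbationLadder(conn, c(0.2, 0.1)), "ascending")
  expect_error(perturbationLadder(conn, c(0.1, 0.2)), "start at 0")
})
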