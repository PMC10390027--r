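# Shared fixtures, all generated in code.

tinyConn <- function(n = 10L, seed = 1L, density = 0.4, normalized = TRUE) {
  conn <- synthConnectome(n, density, seed = seed)
  if (normalized) normalizeSpectral(conn) else conn
}

# temporally smooth multivariate segments (AR(1) per region), the regime
# the one-step estimator is meant for
smoothSegments <- function(nSeg = 8L, n = 4L, len = 30L, rho = 0.95,
                           seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(nSeg), function(i) {
      x <- matrix(0, n, len)
      x[, 1] <- rnorm(n)
      for (t in 2:len) {
        x[, t] <- rho * x[, t - 1] + sqrt(1 - rho^2) * rnorm(n)
      }
      x
    })
  })
}

quickConfig <- function(...) {
  args <- utils::modifyList(
    list(hiddenSize = 16L, nEpochs = 25L, warmup = 5L, batchSize = 16L,
         seed = 7L),
    list(...))
  do.call(estimatorConfig, args)
}
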