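# Internal LSTM machinery for the initial-condition estimator.
#
# Plain-R matrix implementation: a (possibly stacked) LSTM consumes one
# observation per timestep (teacher forcing) and at every timestep emits a
# candidate system state through a linear head; the training loss compares
# the one-interval propagation of that state with the next observation.
# Gradients are exact backprop-through-time, checked against finite
# differences in the test suite.

.sigm <- function(z) 1 / (1 + exp(-z))

# slice a (n x T x B) array at time t into an n x B matrix
.sl <- function(A, t) matrix(A[, t, ], nrow = dim(A)[1])

.lstmInit <- function(nIn, nHidden, nLayers, nOut, distributional = FALSE) {
  glorot <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  layers <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    nx <- if (l == 1L) nIn else nHidden
    b <- numeric(4L * nHidden)
    b[(nHidden + 1L):(2L * nHidden)] <- 1   # forget-gate bias
    layers[[l]] <- list(Wx = glorot(4L * nHidden, nx),
                        Wh = glorot(4L * nHidden, nHidden), b = b)
  }
  par <- list(layers = layers, Wy = glorot(nOut, nHidden), by = numeric(nOut))
  if (distributional) {
    par$Wv <- glorot(nOut, nHidden) * 0.1
    par$bv <- numeric(nOut)
  }
  par
}

# Forward pass. X: nIn x T x B. state: optional list(h, c) of per-layer
# H x B matrices to resume from. Returns outputs Y (nOut x T x B), logVar
# (if distributional), the cache needed for backprop, and the final state.
.lstmForward <- function(par, X, state = NULL, needCache = TRUE) {
  nIn <- dim(X)[1]; T <- dim(X)[2]; B <- dim(X)[3]
  L <- length(par$layers)
  H <- ncol(par$layers[[1]]$Wh)
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); go <- (3 * H + 1):(4 * H)
  if (is.null(state)) {
    h <- lapply(seq_len(L), function(l) matrix(0, H, B))
    cc <- lapply(seq_len(L), function(l) matrix(0, H, B))
  } else {
    h <- state$h; cc <- state$c
  }
  cache <- if (needCache) {
    list(I = list(), F = list(), G = list(), O = list(),
         C = list(), Hs = list(), X = X)
  } else NULL
  if (needCache) {
    for (l in seq_len(L)) {
      cache$I[[l]] <- array(0, c(H, T, B)); cache$F[[l]] <- array(0, c(H, T, B))
      cache$G[[l]] <- array(0, c(H, T, B)); cache$O[[l]] <- array(0, c(H, T, B))
      cache$C[[l]] <- array(0, c(H, T, B)); cache$Hs[[l]] <- array(0, c(H, T, B))
    }
  }
  nOut <- nrow(par$Wy)
  Y <- array(0, c(nOut, T, B))
  LV <- if (!is.null(par$Wv)) array(0, c(nOut, T, B)) else NULL
  for (t in seq_len(T)) {
    inp <- .sl(X, t)
    for (l in seq_len(L)) {
      lay <- par$layers[[l]]
      z <- lay$Wx %*% inp + lay$Wh %*% h[[l]] + lay$b
      i <- .sigm(z[gi, , drop = FALSE]); f <- .sigm(z[gf, , drop = FALSE])
      g <- tanh(z[gg, , drop = FALSE]);  o <- .sigm(z[go, , drop = FALSE])
      cc[[l]] <- f * cc[[l]] + i * g
      h[[l]] <- o * tanh(cc[[l]])
      if (needCache) {
        cache$I[[l]][, t, ] <- i; cache$F[[l]][, t, ] <- f
        cache$G[[l]][, t, ] <- g; cache$O[[l]][, t, ] <- o
        cache$C[[l]][, t, ] <- cc[[l]]; cache$Hs[[l]][, t, ] <- h[[l]]
      }
      inp <- h[[l]]
    }
    Y[, t, ] <- par$Wy %*% h[[L]] + par$by
    if (!is.null(LV)) LV[, t, ] <- par$Wv %*% h[[L]] + par$bv
  }
  list(Y = Y, LV = LV, cache = cache, state = list(h = h, c = cc))
}

# Backprop-through-time. dY (and dLV when distributional) are gradients of
# the scalar loss w.r.t. the outputs, same shape as Y. Returns gradients
# with the same structure as par.
.lstmBackward <- function(par, cache, dY, dLV = NULL) {
  X <- cache$X
  T <- dim(X)[2]; B <- dim(X)[3]
  L <- length(par$layers)
  H <- ncol(par$layers[[1]]$Wh)
  zeroLike <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  gr <- list(layers = lapply(par$layers, function(l) lapply(l, zeroLike)),
             Wy = zeroLike(par$Wy), by = zeroLike(par$by))
  if (!is.null(par$Wv)) { gr$Wv <- zeroLike(par$Wv); gr$bv <- zeroLike(par$bv) }
  dhNext <- lapply(seq_len(L), function(l) matrix(0, H, B))
  dcNext <- lapply(seq_len(L), function(l) matrix(0, H, B))
  for (t in rev(seq_len(T))) {
    dYt <- .sl(dY, t)
    hTop <- .sl(cache$Hs[[L]], t)
    gr$Wy <- gr$Wy + dYt %*% t(hTop)
    gr$by <- gr$by + rowSums(dYt)
    dhHead <- t(par$Wy) %*% dYt
    if (!is.null(dLV)) {
      dLVt <- .sl(dLV, t)
      gr$Wv <- gr$Wv + dLVt %*% t(hTop)
      gr$bv <- gr$bv + rowSums(dLVt)
      dhHead <- dhHead + t(par$Wv) %*% dLVt
    }
    dzAbove <- NULL
    for (l in rev(seq_len(L))) {
      dh <- dhNext[[l]]
      dh <- if (l == L) dh + dhHead
            else dh + t(par$layers[[l + 1]]$Wx) %*% dzAbove
      i <- .sl(cache$I[[l]], t); f <- .sl(cache$F[[l]], t)
      g <- .sl(cache$G[[l]], t); o <- .sl(cache$O[[l]], t)
      cNow <- .sl(cache$C[[l]], t)
      cPrev <- if (t > 1) .sl(cache$C[[l]], t - 1) else matrix(0, H, B)
      tc <- tanh(cNow)
      dO <- dh * tc
      dc <- dh * o * (1 - tc^2) + dcNext[[l]]
      di <- dc * g; dg <- dc * i; df <- dc * cPrev
      dz <- rbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - g^2), dO * o * (1 - o))
      xin <- if (l == 1) .sl(X, t) else .sl(cache$Hs[[l - 1]], t)
      hPrev <- if (t > 1) .sl(cache$Hs[[l]], t - 1) else matrix(0, H, B)
      gl <- gr$layers[[l]]
      gl$Wx <- gl$Wx + dz %*% t(xin)
      gl$Wh <- gl$Wh + dz %*% t(hPrev)
      gl$b <- gl$b + rowSums(dz)
      gr$layers[[l]] <- gl
      dhNext[[l]] <- t(par$layers[[l]]$Wh) %*% dz
      dcNext[[l]] <- dc * f
      dzAbove <- dz
    }
  }
  gr
}

# One-step prediction loss through the propagator Phi. Predictions at
# scored timepoints t in [warmup, T-1] are Phi %*% Y[, t, ], compared with
# X[, t+1, ]. Returns loss and output gradients. Point head: mean squared
# error. Distributional head: diagonal Gaussian negative log-likelihood
# (up to the constant), mean over scored entries.
.onestepLoss <- function(Y, LV, X, Phi, warmup) {
  T <- dim(X)[2]; B <- dim(X)[3]; n <- dim(X)[1]
  scored <- seq(from = warmup, to = T - 1L)
  if (!length(scored)) stop("no scored timepoints: warmup too large for segment")
  N <- length(scored) * B * n
  dY <- array(0, dim(Y))
  dLV <- if (!is.null(LV)) array(0, dim(LV)) else NULL
  tPhi <- t(Phi)
  loss <- 0
  for (t in scored) {
    P <- Phi %*% .sl(Y, t)
    r <- P - .sl(X, t + 1L)
    if (is.null(LV)) {
      loss <- loss + sum(r^2)
      dY[, t, ] <- tPhi %*% (2 * r / N)
    } else {
      lv <- .sl(LV, t)
      elv <- exp(-lv)
      loss <- loss + sum(0.5 * (r^2 * elv + lv))
      dY[, t, ] <- tPhi %*% (r * elv / N)
      dLV[, t, ] <- 0.5 * (1 - r^2 * elv) / N
    }
  }
  list(loss = loss / N, dY = dY, dLV = dLV)
}

# --- Adam over the nested parameter structure ------------------------------

.mapStruct <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) .mapStruct(f, x))
           else Map(function(x, y) .mapStruct(f, x, y), a, b)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

.sumStruct <- function(a, f = function(x) sum(x^2)) {
  if (is.list(a)) sum(vapply(a, .sumStruct, 0, f = f)) else f(a)
}

.adamInit <- function(par) {
  list(m = .mapStruct(function(p) p * 0, par),
       v = .mapStruct(function(p) p * 0, par), t = 0L)
}

.adamStep <- function(par, gr, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- .mapStruct(function(m, g) beta1 * m + (1 - beta1) * g, st$m, gr)
  st$v <- .mapStruct(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, gr)
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  upd <- .mapStruct(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    st$m, st$v)
  par <- .mapStruct(function(p, u) p - u, par, upd)
  list(par = par, state = st)
}

.clipGrads <- function(gr, maxNorm = 5) {
  nrm <- sqrt(.sumStruct(gr))
  if (is.finite(nrm) && nrm > maxNorm) {
    gr <- .mapStruct(function(g) g * (maxNorm / nrm), gr)
  }
  gr
}

# Full training loop on a list of equal-length segments (n x L matrices).
.lstmTrain <- function(segments, Phi, nIn, cfg) {
  L <- unique(vapply(segments, ncol, 1L))
  if (length(L) != 1) stop("training segments must share one length")
  if (cfg@warmup >= L) stop("warmup must be smaller than the segment length")
  B <- length(segments)
  X <- array(0, c(nIn, L, B))
  for (b in seq_len(B)) X[, , b] <- segments[[b]]
  withr::with_seed(cfg@seed, {
    par <- .lstmInit(nIn, cfg@hiddenSize, cfg@nLayers, nIn,
                     distributional = cfg@distributional)
    ad <- .adamInit(par)
    lossCurve <- numeric(0)
    best <- Inf; sinceBest <- 0L
    for (epoch in seq_len(cfg@nEpochs)) {
      ord <- sample.int(B)
      batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
      epochLoss <- 0
      for (bb in batches) {
        Xb <- X[, , bb, drop = FALSE]
        fw <- .lstmForward(par, Xb)
        ls <- .onestepLoss(fw$Y, fw$LV, Xb, Phi, cfg@warmup)
        if (!is.finite(ls$loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d (batch of %d); check data scaling and learning rate",
            epoch, length(bb)))
        }
        gr <- .lstmBackward(par, fw$cache, ls$dY, ls$dLV)
        gr <- .clipGrads(gr)
        stp <- .adamStep(par, gr, ad, cfg@learningRate)
        par <- stp$par; ad <- stp$state
        epochLoss <- epochLoss + ls$loss * length(bb)
      }
      epochLoss <- epochLoss / B
      lossCurve <- c(lossCurve, epochLoss)
      if (epochLoss < best - 1e-7) { best <- epochLoss; sinceBest <- 0L }
      else sinceBest <- sinceBest + 1L
      if (sinceBest >= cfg@patience) break
    }
    list(par = par, lossCurve = lossCurve)
  })
}
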