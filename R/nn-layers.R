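# Internal layer primitives for the residual convolutional regressor.
#
# All activations are stored as dense matrices with rows ordered
# sequence-major: row (b-1)*L + t holds position t of sequence b. Convolution
# is realized as im2col + BLAS matrix multiply; batch normalization is
# per-channel over all rows (batch x positions); max pooling uses valid
# padding. Each function returns the output plus the cache its backward pass
# needs.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

# ---- convolution (same padding, stride 1) ----

.convIdx <- function(B, L, k) {
  Lp <- L + k - 1L
  padl <- (k - 1L) %/% 2L
  baseP <- rep((seq_len(B) - 1L) * Lp, each = L)
  tvec <- rep(seq_len(L), B)
  list(Lp = Lp, padl = padl,
       interior = baseP + padl + tvec,
       slices = lapply(seq_len(k), function(j) baseP + tvec + (j - 1L)))
}

.convForward <- function(X, W, b, k, B, L) {
  Cin <- ncol(X)
  Fout <- ncol(W)
  ix <- .convIdx(B, L, k)
  Xp <- matrix(0, B * ix$Lp, Cin)
  Xp[ix$interior, ] <- X
  Xcol <- matrix(0, B * L, k * Cin)
  for (j in seq_len(k))
    Xcol[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xp[ix$slices[[j]], ]
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(Xcol = Xcol, ix = ix, Cin = Cin, B = B, L = L))
}

.convBackward <- function(dY, W, cache) {
  Cin <- cache$Cin
  ix <- cache$ix
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  dXp <- matrix(0, cache$B * ix$Lp, Cin)
  k <- length(ix$slices)
  for (j in seq_len(k)) {
    idx <- ix$slices[[j]]
    dXp[idx, ] <- dXp[idx, ] + dXcol[, ((j - 1L) * Cin + 1L):(j * Cin)]
  }
  list(dX = dXp[ix$interior, , drop = FALSE], dW = dW, db = db)
}

# ---- batch normalization (shared by conv channels and dense units) ----

# The normalization is applied as a per-column affine map
# Y = X diag(a) + b with a = gamma/sqrt(var + eps), which keeps the hot
# path to one BLAS product and one recycled addition; the backward pass
# recovers the standardized activations algebraically from the cached
# input instead of materializing them.
.bnForward <- function(X, layer, batchStats) {
  N <- nrow(X)
  if (batchStats) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + .BN_EPS)
    layer$rmean <- .BN_MOMENTUM * layer$rmean + (1 - .BN_MOMENTUM) * mu
    layer$rvar <- .BN_MOMENTUM * layer$rvar + (1 - .BN_MOMENTUM) * v
  } else {
    mu <- layer$rmean
    inv <- 1 / sqrt(layer$rvar + .BN_EPS)
  }
  a <- layer$gamma * inv
  Y <- X %*% diag(a, length(a)) + rep(layer$beta - mu * a, each = N)
  list(out = Y, layer = layer,
       cache = list(X = X, mu = mu, inv = inv, batchStats = batchStats))
}

.bnBackward <- function(dY, layer, cache) {
  N <- nrow(dY)
  mu <- cache$mu
  inv <- cache$inv
  dbeta <- colSums(dY)
  sXY <- diag(crossprod(dY, cache$X))
  dgamma <- inv * (sXY - mu * dbeta)
  if (cache$batchStats) {
    # dX = inv*(dxhat - mean(dxhat) - xhat*mean(dxhat*xhat)), expanded so
    # xhat never needs to be formed: dxhat = dY diag(gamma).
    m1 <- layer$gamma * dbeta / N
    m2 <- layer$gamma * inv * (sXY / N - mu * dbeta / N)
    c1 <- layer$gamma * inv
    c2 <- m2 * inv * inv
    const <- -m1 * inv + mu * c2
    dX <- dY %*% diag(c1, length(c1)) - cache$X %*% diag(c2, length(c2)) +
      rep(const, each = N)
  } else {
    dX <- dY %*% diag(layer$gamma * inv, length(inv))
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling (valid padding) ----

.poolOutLen <- function(L, p, w) (L - p) %/% w + 1L

.poolForward <- function(X, p, w, B, L) {
  Fch <- ncol(X)
  Tn <- .poolOutLen(L, p, w)
  baseX <- rep((seq_len(B) - 1L) * L, each = Tn)
  uvec <- rep(seq_len(Tn), B)
  idx1 <- baseX + (uvec - 1L) * w + 1L
  cur <- X[idx1, , drop = FALSE]
  arg <- matrix(1L, nrow(cur), Fch)
  if (p > 1L) for (s in 2:p) {
    cand <- X[idx1 + (s - 1L), , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = cur, cache = list(idx1 = idx1, arg = arg, p = p, B = B, L = L,
                               Tn = Tn, Fch = Fch))
}

.poolBackward <- function(dY, cache) {
  dX <- matrix(0, cache$B * cache$L, cache$Fch)
  for (s in seq_len(cache$p)) {
    sel <- cache$arg == s
    if (!any(sel)) next
    idx <- cache$idx1 + (s - 1L)
    dX[idx, ] <- dX[idx, ] + dY * sel
  }
  dX
}

# ---- flatten: (B*T) x F -> B x (T*F), position-major within channel ----

.flattenForward <- function(X, B, Tn) {
  Fch <- ncol(X)
  H <- t(matrix(aperm(array(X, c(Tn, B, Fch)), c(1, 3, 2)), Tn * Fch, B))
  list(out = H, cache = list(B = B, Tn = Tn, Fch = Fch))
}

.flattenBackward <- function(dH, cache) {
  m <- array(t(dH), c(cache$Tn, cache$Fch, cache$B))
  matrix(aperm(m, c(1, 3, 2)), cache$B * cache$Tn, cache$Fch)
}

# ---- dense / relu / dropout ----

.denseForward <- function(X, W, b) {
  Y <- X %*% W
  list(out = Y + rep(b, each = nrow(Y)), cache = list(X = X))
}

.denseBackward <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

.reluForward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

.dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(X)), nrow(X), ncol(X)) < keep) / keep
  list(out = X * mask, cache = mask)
}

# ---- Glorot-uniform initialization ----

.glorot <- function(fanIn, fanOut, nrow, ncol) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

.newConv <- function(Cin, Fout, k, group) {
  list(type = "conv", group = group, k = k,
       W = .glorot(k * Cin, k * Fout, k * Cin, Fout),
       b = numeric(Fout))
}

.newBN <- function(C, group) {
  list(type = "bn", group = group,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C))
}

.newDense <- function(Din, Dout, group) {
  list(type = "dense", group = group,
       W = .glorot(Din, Dout, Din, Dout),
       b = numeric(Dout))
}

# ---- Adam ----

.adamInit <- function() list(t = 0L, m = list(), v = list())

.adamStep <- function(state, key, param, grad, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- state$m[[key]]
  v <- state$v[[key]]
  if (is.null(m)) { m <- param * 0; v <- param * 0 }
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad * grad
  mhat <- m / (1 - beta1^state$t)
  vhat <- v / (1 - beta2^state$t)
  state$m[[key]] <- m
  state$v[[key]] <- v
  list(state = state, param = param - lr * mhat / (sqrt(vhat) + eps))
}
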