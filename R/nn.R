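# Internal neural-network primitives with explicit forward/backward
# passes. All activations operate on row-major matrices (rows = points or
# particles, columns = channels); heavy lifting is BLAS matrix products.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# PyTorch-style Kaiming-uniform linear initialization: U(-k, k),
# k = 1/sqrt(fan_in), for both weights and biases.
initLinear <- function(fanIn, fanOut) {
  k <- 1 / sqrt(fanIn)
  list(W = matrix(stats::runif(fanIn * fanOut, -k, k), fanIn, fanOut),
       b = stats::runif(fanOut, -k, k))
}

linFwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

# returns list(dX, dW, db)
linBwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

# Batch normalization over rows (one statistic per column).
bnFwdTrain <- function(X, gamma, beta) {
  R <- nrow(X)
  m <- colMeans(X)
  Xc <- X - rep(m, each = R)
  v <- colMeans(Xc^2)                       # biased batch variance
  ivar <- 1 / sqrt(v + BN_EPS)
  Xhat <- Xc * rep(ivar, each = R)
  Y <- Xhat * rep(gamma, each = R) + rep(beta, each = R)
  list(Y = Y, cache = list(Xhat = Xhat, ivar = ivar, gamma = gamma,
                           R = R),
       batchMean = m,
       batchVarUnbiased = if (R > 1) v * R / (R - 1) else v)
}

bnFwdEval <- function(X, gamma, beta, rm, rv) {
  R <- nrow(X)
  sc <- gamma / sqrt(rv + BN_EPS)
  X * rep(sc, each = R) + rep(beta - rm * sc, each = R)
}

bnBwd <- function(dY, cache) {
  R <- cache$R
  Xhat <- cache$Xhat
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- dY * rep(cache$gamma, each = R)
  s1 <- colSums(dXhat)
  s2 <- colSums(dXhat * Xhat)
  dX <- (dXhat - rep(s1 / R, each = R) -
           Xhat * rep(s2 / R, each = R)) * rep(cache$ivar, each = R)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

reluFwd <- function(X) X * (X > 0)
reluBwd <- function(dY, Y) dY * (Y > 0)

tanhFwd <- function(X) tanh(X)
tanhBwd <- function(dY, Y) dY * (1 - Y^2)

# Multi-head self-attention over the point axis of one particle.
# X: n x C; weights Wq/Wk/Wv/Wo: C x C; nHeads divides C.
# Residual connection: output = X + attention(X).
attnFwd <- function(X, W, nHeads) {
  n <- nrow(X); C <- ncol(X)
  dk <- C %/% nHeads
  Q <- linFwd(X, W$Wq, W$bq)
  K <- linFwd(X, W$Wk, W$bk)
  V <- linFwd(X, W$Wv, W$bv)
  O <- matrix(0, n, C)
  A <- vector("list", nHeads)
  sc <- 1 / sqrt(dk)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * sc
    S <- S - apply(S, 1, max)                 # row-stable softmax
    E <- exp(S)
    Ah <- E / rowSums(E)
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
    A[[h]] <- Ah
  }
  Y <- linFwd(O, W$Wo, W$bo)
  list(Y = X + Y, cache = list(X = X, Q = Q, K = K, V = V, O = O,
                               A = A, dk = dk, nHeads = nHeads))
}

attnBwd <- function(dOut, cache, W) {
  X <- cache$X; n <- nrow(X); C <- ncol(X)
  dk <- cache$dk; sc <- 1 / sqrt(dk)
  lo <- linBwd(dOut, cache$O, W$Wo)
  dO <- lo$dX
  dQ <- matrix(0, n, C); dK <- matrix(0, n, C); dV <- matrix(0, n, C)
  for (h in seq_len(cache$nHeads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- Ah * (dA - rowSums(dA * Ah))        # softmax backward
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) * sc
    dK[, idx] <- (crossprod(dS, cache$Q[, idx, drop = FALSE])) * sc
  }
  lq <- linBwd(dQ, X, W$Wq)
  lk <- linBwd(dK, X, W$Wk)
  lv <- linBwd(dV, X, W$Wv)
  list(dX = dOut + lq$dX + lk$dX + lv$dX,
       dWq = lq$dW, dbq = lq$db, dWk = lk$dW, dbk = lk$db,
       dWv = lv$dW, dbv = lv$db, dWo = lo$dW, dbo = lo$db)
}
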