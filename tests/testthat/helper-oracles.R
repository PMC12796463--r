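# Independent oracles and small fixtures shared across tests. Oracles are
# deliberately naive (double loops, explicit ranks) so they cannot share
# code paths with the implementation they check.

# O(N * Nhat) double-loop Chamfer distance, normalized by |X|
bruteChamfer <- function(X, Xhat) {
  n <- nrow(X); m <- nrow(Xhat)
  d1 <- 0
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(m))
      best <- min(best, sum((X[i, ] - Xhat[j, ])^2))
    d1 <- d1 + best
  }
  d2 <- 0
  for (j in seq_len(m)) {
    best <- Inf
    for (i in seq_len(n))
      best <- min(best, sum((X[i, ] - Xhat[j, ])^2))
    d2 <- d2 + best
  }
  (d1 + d2) / n
}

# Spearman rho via explicitly constructed average ranks + product-moment
# formula, no call into cor(method = "spearman")
bruteSpearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# tiny architecture used wherever full width is unnecessary
tinyConfig <- function(p = 2, d = 3, Ns = 6L)
  pcvaeConfig(p = p, d = d, encoderWidths = c(4L, 6L, 8L),
              headWidth = 5L, decoderWidths = c(4L, 6L, 8L),
              nHeads = 2L, nOutputPoints = Ns, indexEmbedDim = 3L)

# exact ring of n points, radius r, first point at angle phase
ringPoints <- function(n, r, phase = 0) {
  a <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(a), r * sin(a))
}

# random particle set for round-trip style tests
randomParticleSet <- function(nParticles = 10, p = 2, seed = 1) {
  set.seed(seed)
  particleSet(lapply(seq_len(nParticles), function(i)
    matrix(stats::rnorm(sample(3:12, 1) * p, sd = 40), ncol = p)))
}
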