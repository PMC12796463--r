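test_that("configuration invariants are enforced", {
  expect_error(pcvaeConfig(p = 4), "p must be")
  expect_error(pcvaeConfig(p = 2, d = 0), "d must be")
  expect_error(pcvaeConfig(p = 2, nHeads = 3L), "divide")
  cfg <- pcvaeConfig(p = 2)
  expect_equal(cfg$d, 8L)
  expect_equal(cfg$encoderWidths, c(64L, 128L, 1024L))
  expect_equal(cfg$decoderWidths, c(256L, 512L, 1024L))
  expect_equal(cfg$nHeads, 4L)
})

test_that("encoding is invariant to localization order", {
  set.seed(21)
  m <- pcvae(pcvaeConfig(p = 2), seed = 21)   # random weights
  X <- matrix(runif(80 * 2, -1, 1), 80, 2)
  ref <- encodeParticle(m, X)
  for (k in 1:20) {
    perm <- sample(nrow(X))
    e <- encodeParticle(m, X[perm, ])
    expect_equal(e$mu, ref$mu, tolerance = 1e-5)
    expect_equal(e$sigma, ref$sigma, tolerance = 1e-5)
  }
})

test_that("duplicating every point leaves the mean-pooled code unchanged", {
  set.seed(22)
  m <- pcvae(tinyConfig(), seed = 22)
  X <- matrix(runif(12, -1, 1), 6, 2)
  a <- encodeParticle(m, X)
  b <- encodeParticle(m, rbind(X, X))
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  expect_equal(a$sigma, b$sigma, tolerance = 1e-12)
})

test_that("a zero network encodes to the standard normal posterior", {
  m <- pcvae(tinyConfig(), seed = 23)
  m@env$params <- lapply(m@env$params, function(p) p * 0)
  e <- encodeParticle(m, matrix(runif(10, -1, 1), 5, 2))
  expect_equal(e$mu, rep(0, 3))
  expect_equal(e$sigma, rep(1, 3))
})

test_that("reparameterization is the elementwise affine transform", {
  expect_equal(reparameterize(c(1, 2), c(1, 1), c(0.5, -0.5)),
               c(1.5, 1.5))
  expect_equal(reparameterize(c(3, 4), c(2, 2), c(0, 0)), c(3, 4))
  expect_error(reparameterize(1, -1, 0), "positive")
  set.seed(24)
  z <- replicate(1e5, reparameterize(2, 0.5))
  expect_lt(abs(mean(z) - 2), 3 * 0.5 / sqrt(1e5))
  expect_lt(abs(sd(z) - 0.5), 3 * 0.5 / sqrt(2 * 1e5))
})

test_that("decoding returns a bounded fixed-size cloud, deterministically", {
  m <- pcvae(tinyConfig(Ns = 9L), seed = 25)
  z <- rnorm(3)
  a <- decodeLatent(m, z)
  expect_equal(dim(a), c(9L, 2L))
  expect_true(all(abs(a) < 1))
  expect_identical(a, decodeLatent(m, z))
  expect_error(decodeLatent(m, rnorm(5)), "shape")
})

test_that("the full forward pass is seeded and permutation-stable", {
  m <- pcvae(tinyConfig(), seed = 26)
  X <- matrix(runif(40, -1, 1), 20, 2)
  f1 <- pcvaeForward(m, X, seed = 1)
  f2 <- pcvaeForward(m, X, seed = 1)
  expect_identical(f1$reconstruction, f2$reconstruction)
  # same eps, permuted input: same latent and reconstruction
  eps <- rnorm(3)
  a <- pcvaeForward(m, X, eps = eps)
  b <- pcvaeForward(m, X[sample(20), ], eps = eps)
  expect_equal(a$mu, b$mu, tolerance = 1e-5)
  expect_equal(a$reconstruction, b$reconstruction, tolerance = 1e-4)
  # output size does not depend on input size
  expect_equal(nrow(pcvaeForward(m, X[1:3, ], seed = 2)$reconstruction),
               6L)
})

test_that("analytic gradients match central finite differences", {
  set.seed(27)
  cfg <- tinyConfig()
  m <- pcvae(cfg, seed = 27)
  B <- 2; n <- 5
  Xlist <- lapply(1:B, function(i) matrix(runif(n * 2, -1, 1), n, 2))
  eps <- matrix(rnorm(B * cfg$d), B, cfg$d)
  beta <- 0.41
  fb <- pcvae:::batchForwardBackward(cfg, m@env$params, m@env$running,
                                     Xlist, eps, beta)
  lossAt <- function(params)
    pcvae:::batchForwardBackward(cfg, params, m@env$running, Xlist,
                                 eps, beta)$total
  h <- 1e-6
  for (nm in names(m@env$params)) {
    P <- m@env$params[[nm]]
    G <- fb$grads[[nm]]
    expect_false(is.null(G), info = nm)
    idx <- sample(length(P), min(4, length(P)))
    for (i in idx) {
      pp <- m@env$params
      pp[[nm]][i] <- P[i] + h
      up <- lossAt(pp)
      pp[[nm]][i] <- P[i] - h
      dn <- lossAt(pp)
      num <- (up - dn) / (2 * h)
      # normalized error with an absolute floor: biases feeding
      # batch-norm have an exactly-zero gradient that finite
      # differences can only reproduce to rounding noise
      err <- abs(G[i] - num) / max(1e-6, abs(G[i]) + abs(num))
      expect_lt(err, 5e-4)
    }
  }
  # gradient flow: finite, and nonzero for both encoder and decoder
  expect_gt(sum(abs(fb$grads$enc1W)), 0)
  expect_gt(sum(abs(fb$grads$outW)), 0)
  expect_true(all(vapply(fb$grads, function(g) all(is.finite(g)), NA)))
})

test_that("checkpoints round-trip the model exactly", {
  m <- pcvae(tinyConfig(), seed = 28)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  X <- matrix(runif(16, -1, 1), 8, 2)
  expect_identical(encodeParticle(m, X), encodeParticle(m2, X))
  ck <- list(format = "something-else")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(ck, bad)
  expect_error(loadCheckpoint(bad), "not a pcvae checkpoint")
})
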