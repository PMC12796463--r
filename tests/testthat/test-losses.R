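test_that("Chamfer distance matches hand-computed values", {
  X <- rbind(c(0, 0), c(1, 0))
  expect_equal(chamferDistance(X, X), 0)
  expect_equal(chamferDistance(rbind(c(0, 0)), rbind(c(3, 4))), 50)
  expect_equal(chamferDistance(X, rbind(c(0, 0))), 0.5)
  expect_error(chamferDistance(X[0, , drop = FALSE], X), "non-empty")
})

test_that("Chamfer distance equals the brute-force double loop", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(1:50, 1); m <- sample(1:50, 1)
    p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(m * p), m, p)
    expect_equal(chamferDistance(X, Y), bruteChamfer(X, Y),
                 tolerance = 1e-12)
  }
})

test_that("Chamfer is nonnegative, zero only for equal sets", {
  set.seed(12)
  X <- matrix(rnorm(16), 8, 2)
  expect_equal(chamferDistance(X, X[sample(8), ]), 0)
  Y <- X; Y[1, 1] <- Y[1, 1] + 0.5
  expect_gt(chamferDistance(X, Y), 0)
})

test_that("the analytic Chamfer gradient matches finite differences", {
  set.seed(13)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(8), 4, 2)
  g <- pcvae:::chamferGradXhat(X, Y)
  h <- 1e-6
  for (i in seq_along(Y)) {
    Yp <- Y; Yp[i] <- Yp[i] + h
    Ym <- Y; Ym[i] <- Ym[i] - h
    num <- (chamferDistance(X, Yp) - chamferDistance(X, Ym)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("KLD closed form matches its reference values", {
  expect_equal(kldGaussian(rep(0, 5), rep(1, 5)), 0)
  expect_equal(kldGaussian(1, 1), 0.5)
  expect_equal(kldGaussian(0, sqrt(exp(1))), (exp(1) - 2) / 2)
  expect_error(kldGaussian(0, -1), "positive")
})

test_that("KLD agrees with a Monte-Carlo divergence estimate", {
  set.seed(14)
  mu <- 0.7; sigma <- 1.3
  z <- rnorm(1e5, mu, sigma)
  samp <- dnorm(z, mu, sigma, log = TRUE) - dnorm(z, 0, 1, log = TRUE)
  se <- sd(samp) / sqrt(length(samp))
  expect_lt(abs(mean(samp) - kldGaussian(mu, sigma)), 3 * se)
})

test_that("the KLD warm-up schedule has the documented shape", {
  cfg <- lossConfig(betaMax = 2, warmupSteps = 5000L)
  expect_equal(betaSchedule(2500, cfg), 1)      # midpoint: beta_max / 2
  expect_lte(betaSchedule(0, cfg), 0.01 * 2)
  expect_gte(betaSchedule(5000, cfg), 0.99 * 2)
  b <- betaSchedule(0:10000, cfg)
  expect_true(all(diff(b) >= 0))
  expect_equal(betaSchedule(c(0, 3, 999), lossConfig(1, 0L)),
               rep(1, 3))
})

test_that("the total loss is the scheduled composition of its parts", {
  set.seed(15)
  X <- matrix(rnorm(12), 6, 2)
  Y <- matrix(rnorm(10), 5, 2)
  mu <- rnorm(4); sigma <- exp(rnorm(4) / 4)
  cfg <- lossConfig(betaMax = 0.3, warmupSteps = 100L)
  tl <- totalLoss(X, Y, mu, sigma, step = 40L, cfg)
  expect_equal(tl$total,
               chamferDistance(X, Y) +
                 betaSchedule(40L, cfg) * kldGaussian(mu, sigma),
               tolerance = 1e-12)
  # beta_max = 0 reduces to the reconstruction term
  tl0 <- totalLoss(X, Y, mu, sigma, step = 40L, lossConfig(0, 100L))
  expect_equal(tl0$total, chamferDistance(X, Y))
  # both terms vanish at the fixed point
  expect_equal(totalLoss(X, X, rep(0, 4), rep(1, 4))$total, 0)
})
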