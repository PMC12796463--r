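test_that("2D radius: exact on noiseless rings, symmetric pairs", {
  expect_equal(estimateRadius2D(ringPoints(8, 55))$value, 55)
  expect_equal(estimateRadius2D(rbind(c(3, 0), c(-3, 0)))$value, 3)
  expect_error(estimateRadius2D(matrix(0, 1, 2)), "insufficient")
})

test_that("2D radial mean reproduces the sigma^2/(2R) noise bias", {
  set.seed(31)
  R <- 50; s <- 3; n <- 1e5
  a <- runif(n, 0, 2 * pi)
  pts <- cbind(R * cos(a), R * sin(a)) + matrix(rnorm(2 * n, 0, s), n)
  est <- estimateRadius2D(pts)
  r <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  se <- sd(r) / sqrt(n)
  expect_lt(abs(est$value - (R + s^2 / (2 * R))), 3 * se)
})

test_that("3D radius: cylinder median, robust to axial outliers", {
  set.seed(32)
  a <- 2 * pi * (0:999) / 1000          # balanced angles: centroid at 0
  pts <- cbind(55 * cos(a), 55 * sin(a), rnorm(1000, 0, 20))
  pts[, 3] <- pts[, 3] - mean(pts[, 3])
  expect_equal(estimateRadius3D(pts)$value, 55, tolerance = 1e-9)
  # contaminate 10% at r = 200 (directions balanced so the centroid
  # stays put): median moves < 1 nm
  bad <- pts
  idx <- seq(1, 1000, by = 10)
  bad[idx, 1:2] <- cbind(200 * cos(a[idx]), 200 * sin(a[idx]))
  expect_lt(abs(estimateRadius3D(bad)$value - 55), 1)
  # the mean-based statistic, by contrast, is pulled far off
  rb <- sqrt(rowSums(sweep(bad, 2, colMeans(bad))[, 1:2]^2))
  expect_gt(abs(mean(rb) - 55), 10)
})

test_that("median convention is the midpoint of the middle pair", {
  pts <- cbind(c(1, 2, 3, 4), 0, 0)
  ctr <- sweep(pts, 2, colMeans(pts))
  expect_equal(estimateRadius3D(pts)$value,
               median(abs(ctr[, 1])))
})

test_that("NPC height: median split of the z histogram", {
  z <- rep(c(-24.25, 24.25), each = 50)
  pts <- cbind(rnorm(100), rnorm(100), z)
  expect_equal(estimateHeightNPC3D(pts)$value, 48.5)
  # translation invariance
  expect_equal(estimateHeightNPC3D(sweep(pts, 2, c(0, 0, -17),
                                         "+"))$value, 48.5)
  set.seed(33)
  zg <- c(rnorm(5000, -24.25, 3), rnorm(5000, 24.25, 3))
  ptsg <- cbind(rnorm(1e4), rnorm(1e4), zg)
  se <- 3 * sqrt(pi / 2) / sqrt(5000)   # se of a Gaussian median
  expect_lt(abs(estimateHeightNPC3D(ptsg)$value - 48.5), 2 * 3 * se)
  expect_error(estimateHeightNPC3D(cbind(0, 0, c(1, 1, 1))),
               "one side")
})

test_that("tetrahedron height: EM separates base plate and apex", {
  z <- c(rep(0, 3000), rep(90, 1000))
  pts <- cbind(rnorm(4000), rnorm(4000), z)
  expect_equal(estimateHeightTetrahedron(pts)$value, 90,
               tolerance = 1e-6)
  set.seed(34)
  z2 <- c(rnorm(7500, 0, 2), rnorm(2500, 60, 2))
  pts2 <- cbind(rnorm(1e4), rnorm(1e4), z2)
  est <- estimateHeightTetrahedron(pts2)
  se <- sqrt(4 / 7500 + 4 / 2500)
  expect_lt(abs(est$value - 60), 3 * se)
})

test_that("the EM mixture agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(35)
  z <- c(rnorm(2000, 10, 4), rnorm(1000, 70, 6))
  fit <- pcvae:::gaussianMixture2(z)
  mc <- Mclust(z, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("FWHM-based precision follows the Gaussian reference", {
  set.seed(36)
  x <- rnorm(100, 0, 10)
  # FWHM / sqrt(N) = 2.3548 * sigma / 10; robust-sigma sampling error
  se <- 1.166 * 10 / sqrt(100)
  expect_lt(abs(estimatePrecision(x) - 2.3548), 3 * 2.3548 / 10 * se)
  # quadrupling N at fixed spread halves the value exactly
  expect_equal(estimatePrecision(rep(x, 4)),
               estimatePrecision(x) / 2)
  expect_equal(estimatePrecision(rep(5, 10)), 0)
})

test_that("estimators are invariant to z-rotation and translation", {
  set.seed(37)
  phys <- photophysics(dol = 1, meanLocsPerSite = 30,
                       locPrecisionNm = 2)
  sp <- simulateParticle(structureModel("double_ring3d"), phys)
  pts <- sp$points
  for (k in 1:5) {
    mv <- pcvae:::rotatePoints(pts, runif(1, 0, 2 * pi))
    mv <- sweep(mv, 2, rnorm(3, 0, 100), "+")
    expect_equal(estimateRadius3D(mv)$value,
                 estimateRadius3D(pts)$value, tolerance = 1e-9)
    expect_equal(estimateHeightNPC3D(mv)$value,
                 estimateHeightNPC3D(pts)$value, tolerance = 1e-9)
  }
})

test_that("dataset-level estimation returns NA for unestimable particles", {
  ps <- particleSet(list(cbind(rnorm(50), rnorm(50), rnorm(50)),
                         cbind(rnorm(5), rnorm(5), 7)))  # flat in z
  expect_warning(df <- estimateParameters(ps, "npc3d-height"),
                 "could not be estimated")
  expect_true(is.na(df$value_nm[2]))
  expect_false(is.na(df$value_nm[1]))
})
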