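test_that("equal-count binning follows the ceil-partition rule", {
  lat <- matrix(rnorm(218 * 8), 218, 8)
  ba <- orderAndBin(lat, dim = 3, nBins = 20)
  sizes <- lengths(ba$bins)
  expect_equal(sizes, c(rep(11L, 19), 9L))

  sizes2 <- lengths(orderAndBin(matrix(rnorm(1399)), 1, 20)$bins)
  expect_equal(sizes2, c(rep(70L, 19), 69L))

  sizes3 <- lengths(orderAndBin(matrix(rnorm(20)), 1, 20)$bins)
  expect_equal(sizes3, rep(1L, 20))

  expect_error(orderAndBin(matrix(rnorm(10)), 1, 20), "at least")
})

test_that("bins partition the particles in nondecreasing latent order", {
  set.seed(41)
  lat <- matrix(rnorm(75 * 4), 75, 4)
  ba <- orderAndBin(lat, dim = 2, nBins = 10)
  expect_setequal(unlist(ba$bins), 1:75)
  expect_equal(anyDuplicated(unlist(ba$bins)), 0L)
  v <- lat[ba$order, 2]
  expect_true(all(diff(v) >= 0))
  # stable tie handling: ties keep original index order
  lat2 <- matrix(c(rep(1, 5), 0, 0, 0), 8, 1)
  expect_equal(orderAndBin(lat2, 1, 4)$order, c(6:8, 1:5))
})

test_that("z-rotation registration recovers a known misalignment", {
  ring <- ringPoints(8, 50)
  rotated <- pcvae:::rotatePoints(ring, 10 * pi / 180)
  sp <- registerBin(list(ring, rotated), mode = "rot_z", gridDeg = 2)
  expect_equal(nrow(sp$points), 16)
  post <- chamferDistance(ring, sp$points[9:16, ])
  pre <- chamferDistance(ring, rotated)
  expect_lte(post, pre)
  expect_lt(post, 1e-6)          # 8-fold ring: exact recovery mod 45 deg
  # recovered angle equivalent to -10 deg modulo the ring symmetry
  ang <- (sp$rotationsRad[2] %% (pi / 4)) * 180 / pi
  expect_true(min(abs(ang - 35), abs(ang - 35 - 45)) < 0.5 ||
                abs(ang) < 0.5)
})

test_that("registration identity and union modes behave as stated", {
  ring <- ringPoints(6, 30)
  one <- registerBin(list(ring))
  expect_identical(one$points, ring)
  both <- registerBin(list(ring, ring + 1), mode = "none")
  expect_equal(nrow(both$points), 12)
  expect_identical(both$points[7:12, ], ring + 1)
  expect_error(registerBin(list()), "empty")
})

test_that("super-particle point counts add up over bin members", {
  set.seed(42)
  sim <- simulateDataset(structureModel("ring2d"),
                         photophysics(locPrecisionNm = 1),
                         radius = hetUniform(40, 60), nParticles = 12,
                         seed = 5)
  lat <- matrix(rnorm(12 * 2), 12, 2)
  ba <- orderAndBin(lat, 1, nBins = 3)
  sps <- superParticles(sim$dataset, ba, mode = "rot_z", gridDeg = 10)
  for (b in seq_along(sps))
    expect_equal(nrow(sps[[b]]$points),
                 sum(nLocalizations(sim$dataset)[ba$bins[[b]]]))
})

test_that("correlations match direct references including rank behavior", {
  set.seed(43)
  lat <- matrix(rnorm(40 * 3), 40, 3)
  par <- 2 * lat[, 1] + 1
  co <- correlateLatent(lat, par)
  expect_equal(co$pearson[1], 1)
  expect_equal(co$spearman[1], 1)
  # monotone nonlinear: rank correlation 1, linear below 1
  par3 <- lat[, 2]^3
  co3 <- correlateLatent(lat, par3)
  expect_equal(co3$spearman[2], 1)
  expect_lt(abs(co3$pearson[2]), 1)
  # degenerate input flagged undefined
  cc <- correlateLatent(lat, rep(5, 40))
  expect_false(any(cc$defined))
  expect_true(all(is.na(cc$pearson)))
})

test_that("Spearman agrees with a brute-force rank implementation", {
  set.seed(44)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE)   # forces ties
    y <- rnorm(n)
    expect_equal(cor(x, y, method = "spearman"), bruteSpearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("robustness subsampling honours its contracts", {
  ps <- particleSet(list(matrix(rnorm(200), 100, 2),
                         matrix(rnorm(60), 30, 2)))
  expect_error(robustnessCurve(ps, c(0.5, 1), NULL, NULL, 1:2),
               "descending")
  expect_error(robustnessCurve(ps, c(1, 0), NULL, NULL, 1:2),
               "ratios")
  sub <- subsampleLocalizations(ps, 0.5, seed = 3)
  expect_equal(nLocalizations(sub), c(50L, 15L))
})
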