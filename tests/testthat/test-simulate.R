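test_that("zero-noise ring particles lie exactly on the nominal circle", {
  set.seed(1)
  sp <- simulateParticle(structureModel("ring2d", radiusNm = 55),
                         photophysics(dol = 1, meanLocsPerSite = 5,
                                      locPrecisionNm = 0))
  r <- sqrt(rowSums(sp$points^2))  # site centroid is the origin
  expect_equal(r, rep(55, nrow(sp$points)), tolerance = 1e-12)
  expect_equal(sp$nLabeledSites, 8L)
})

test_that("zero-noise tetrahedra have exactly two z levels separated by height", {
  set.seed(2)
  sp <- simulateParticle(structureModel("tetrahedron3d", heightNm = 90),
                         photophysics(dol = 1, meanLocsPerSite = 4,
                                      locPrecisionNm = 0))
  z <- sort(unique(round(sp$points[, 3], 9)))
  expect_length(z, 2)
  expect_equal(diff(z), 90)
})

test_that("labeling follows the degree-of-labeling Bernoulli law", {
  set.seed(3)
  lab <- vapply(1:10000, function(i)
    simulateParticle(structureModel("ring2d"),
                     photophysics(dol = 0.5, meanLocsPerSite = 1,
                                  locPrecisionNm = 0))$nLabeledSites,
    0L)
  # mean of Binomial(8, 0.5) conditioned >= 1: 4 / (1 - 0.5^8)
  expected <- 4 / (1 - 0.5^8)
  se <- sqrt(2) / sqrt(10000)      # binomial sd = sqrt(8 * .25)
  expect_lt(abs(mean(lab) - expected), 3 * se)
})

test_that("localization counts match n_sites * dol * E[truncated count]", {
  set.seed(4)
  phys <- photophysics(dol = 0.8, meanLocsPerSite = 3,
                       locPrecisionNm = 0)
  n <- vapply(1:4000, function(i)
    nrow(simulateParticle(structureModel("ring2d"), phys)$points), 0L)
  m <- 3
  expected <- 8 * 0.8 * m / (1 - exp(-m)) / (1 - (1 - 0.8)^8)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("datasets record aligned ground truth and are seed-reproducible", {
  sim <- simulateDataset(structureModel("ring2d"), photophysics(),
                         radius = hetFixed(50), nParticles = 10,
                         seed = 9)
  expect_equal(sim$truth$radius_nm, rep(50, 10))
  expect_equal(sim$truth$n_localizations, nLocalizations(sim$dataset))

  sim2 <- simulateDataset(structureModel("ring2d"), photophysics(),
                          radius = hetFixed(50), nParticles = 10,
                          seed = 9)
  expect_identical(lapply(particles(sim$dataset), identity),
                   lapply(particles(sim2$dataset), identity))

  big <- simulateDataset(structureModel("ring2d"),
                         photophysics(dol = 1, meanLocsPerSite = 2,
                                      locPrecisionNm = 0),
                         radius = hetUniform(45, 65),
                         nParticles = 2000, seed = 10)
  se <- (65 - 45) / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(big$truth$radius_nm) - 55), 3 * se)
})

test_that("double-ring scaffold separates two 16-site rings by the height", {
  s <- pcvae:::scaffoldSites(structureModel("double_ring3d",
                                            radiusNm = 55,
                                            heightNm = 48.5))
  expect_equal(nrow(s), 32)
  expect_equal(sort(unique(s[, 3])), c(-24.25, 24.25))
  expect_equal(sqrt(s[, 1]^2 + s[, 2]^2), rep(55, 32))
})

test_that("rotation does not change rotation-invariant estimators", {
  set.seed(6)
  phys <- photophysics(dol = 1, meanLocsPerSite = 20,
                       locPrecisionNm = 0, countLaw = "fixed")
  p1 <- simulateParticle(structureModel("ring2d", radiusNm = 40), phys,
                         rotate = FALSE)$points
  p2 <- pcvae:::rotatePoints(p1, 1.23)
  expect_equal(estimateRadius2D(p1)$value, estimateRadius2D(p2)$value,
               tolerance = 1e-9)
})

test_that("presets emulate the documented localization budgets", {
  sim <- smlmPreset("npc2d", nParticles = 150, seed = 11)
  expect_true(abs(mean(sim$truth$n_localizations) - 150) < 25)
  expect_equal(spatialDim(sim$dataset), 2L)
  sim3 <- smlmPreset("npc3d", nParticles = 150, seed = 12)
  expect_true(abs(mean(sim3$truth$n_localizations) - 80) < 15)
  expect_equal(spatialDim(sim3$dataset), 3L)
})
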