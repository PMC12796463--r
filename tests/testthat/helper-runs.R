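# Cached end-to-end training runs shared between acceptance tests, so
# the headline 2D-ring recovery and the subsampling-robustness check use
# one and the same full-data training (as the robustness experiment
# prescribes: identical settings, only the localization fraction varies).

.runCache <- new.env(parent = emptyenv())

# study conditions for the 2D NPC analog: 400 ring particles,
# radius ~ U(45, 65) nm, ~150 localizations/particle, 3 nm precision
npc2dStudy <- function() {
  if (is.null(.runCache$npc2d)) {
    sim <- simulateDataset(
      structureModel("ring2d"),
      photophysics(dol = 0.8, meanLocsPerSite = 24, locPrecisionNm = 3),
      radius = hetUniform(45, 65), nParticles = 400, seed = 101)
    norm <- normalizeParticles(sim$dataset)
    fit <- trainPCVAE(norm, pcvaeConfig(p = 2), trainConfig(seed = 202))
    lat <- encodeDataset(fit$model, norm)
    co <- correlateLatent(lat$mu, sim$truth$radius_nm)
    .runCache$npc2d <- list(sim = sim, fit = fit, latents = lat,
                            correlations = co)
  }
  .runCache$npc2d
}

# study conditions for the DNA-origami tetrahedron analog: 220
# particles, height ~ U(45, 95) nm, PAINT-scale localization counts
tetraStudy <- function() {
  if (is.null(.runCache$tetra)) {
    sim <- smlmPreset("tetra3d", nParticles = 220, seed = 303)
    norm <- normalizeParticles(sim$dataset)
    fit <- trainPCVAE(norm, pcvaeConfig(p = 3), trainConfig(seed = 404))
    lat <- encodeDataset(fit$model, norm)
    co <- correlateLatent(lat$mu, sim$truth$height_nm)
    .runCache$tetra <- list(sim = sim, fit = fit, latents = lat,
                            correlations = co)
  }
  .runCache$tetra
}
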