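# pcvae

Detects **continuous structural heterogeneity** in single-molecule
localization microscopy (SMLM) particle datasets with a point-cloud
variational auto-encoder, entirely in R.

SMLM particle fusion merges hundreds of segmented copies of a structure
(nuclear pore complexes, DNA-origami nanostructures) into one
high-signal super-particle — under the assumption that all copies are
identical. Real structures vary continuously in radius, height or
conformation, and that variation is exactly what fusion averages away.
`pcvae` works directly on the localization point clouds
`X ∈ R^{N×p}` (p = 2, 3; coordinates in nm): a permutation-invariant
encoder (shared per-point MLPs 64/128/1024 with batch-norm + ReLU,
mean pooling) maps each particle to a latent Gaussian `(μ, σ) ∈ R^8`;
a latent draw `z = μ + σ ⊙ ε` feeds a decoder (fully connected
256/512/1024 with Tanh + skip connection, per-point 1×1 convolutions
and 4-head self-attention) that reconstructs a normalized point cloud.
Training minimizes

```
L = CD(X, X̂) + β(t) · KL( N(μ, σ²) ‖ N(0, I) )
```

with `CD` the symmetric Chamfer distance normalized by `|X|`, and
`β(t)` a sigmoid warm-up over the first 5000 steps (Adam, lr 1e-4,
weight decay 1e-5, batches of 8 particles, 4 epochs). After training,
particles ordered along single latent dimensions expose the dominant
modes of variation; 20 equal-count bins are registered into
super-particles, and independent model-based estimators (radial mean /
median, median z-split, two-Gaussian EM on the z histogram, FWHM-based
precision) validate the ordering. A synthetic SMLM simulator (8-site
ring, 32-site double ring, 4-site tetrahedron; stochastic labeling,
zero-truncated Poisson localization counts, Gaussian localization
noise, random in-plane rotation) provides ground-truth datasets so the
whole pipeline runs self-contained.

The neural network — forward passes, backpropagation, Adam — is
implemented in base-R matrix algebra (BLAS); a finite-difference
gradient check over every parameter tensor is part of the test suite.

## Worked example

```r
library(pcvae)

# 100 ring particles (2D NPC analog), radius ~ U(45, 65) nm,
# ~150 localizations/particle, 3 nm localization precision
sim <- simulateDataset(structureModel("ring2d"),
                       photophysics(dol = 0.8, meanLocsPerSite = 24,
                                    locPrecisionNm = 3),
                       radius = hetUniform(45, 65),
                       nParticles = 100, seed = 7)
sim$dataset
#> ParticleSet with 100 particles (p = 2)
#>   localizations per particle: 81-212 (median 154.5)
#>   normalized: FALSE (scale 1 nm)

# model-based radius per particle (mean radial coordinate, FWHM-based
# standard error)
est <- estimateParameters(sim$dataset, "npc2d")
head(est, 3)
#>   particle_id value_nm precision_nm n_locs
#> 1           1 64.66579    0.9336108    172
#> 2           2 48.61232    2.9088689    124
#> 3           3 45.43488    1.7609945    152

cor(est$value_nm, sim$truth$radius_nm)
#> [1] 0.911808
```

The estimated radii track the generator's ground truth (r = 0.91 at
~150 localizations/particle; the residual scatter is the estimator's
intrinsic sampling noise). Training and latent analysis on a
full-size study (400 particles, a few minutes on one core):

```r
norm <- normalizeParticles(sim$dataset)       # center + one global scale
fit  <- trainPCVAE(norm, pcvaeConfig(p = 2), trainConfig(seed = 1))
lat  <- encodeDataset(fit$model, norm)        # n x 8 latent means
correlateLatent(lat$mu, est$value_nm)         # Pearson/Spearman per dim
bins <- orderAndBin(lat$mu, dim = 1, nBins = 20)
sp   <- superParticles(sim$dataset, bins)     # registered bin clouds
```

At the 400-particle scale of the shipped study conditions, the best
latent dimension reaches |Spearman| ≈ 0.88 against the true radius
(`tests/testthat/test-acceptance.R` asserts ≥ 0.7), and the detection
survives randomly discarding half of all localizations.

`runPipeline()` (or the thin CLI `inst/cli/pcvae.R` with subcommands
`simulate | train | analyze | estimate | robustness | run`) chains the
stages with one root seed and writes dataset, checkpoint, history,
correlation report, bin membership and a manifest into a run directory.

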