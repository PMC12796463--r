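#' Normalize a ParticleSet for network input
#'
#' Each particle is centered at its own centroid (translation carries no
#' structural information), then all particles are divided by one global
#' scale \eqn{s = \max_i \max_j \lVert x_{ij} \rVert_2} (the largest
#' post-centering point norm in the whole set). A single global scale —
#' rather than per-particle scaling — preserves relative particle sizes,
#' which is exactly the heterogeneity the latent space must detect.
#' After normalization every coordinate lies in \eqn{[-1, 1]}, matching
#' the bounded Tanh output range of the decoder.
#'
#' @param x an un-normalized [ParticleSet-class].
#' @return A normalized \code{ParticleSet} with \code{scaleNm = s} and the
#'   removed centroids stored for exact inversion by
#'   [denormalizeParticles()].
#' @examples
#' ring <- function(r) cbind(r * cos(1:8), r * sin(1:8))
#' ps <- particleSet(list(ring(50), ring(100)))
#' ns <- normalizeParticles(ps)
#' scaleNm(ns)  # 100
#' @export
normalizeParticles <- function(x) {
  stopifnot(is(x, "ParticleSet"))
  if (isNormalized(x)) stop("dataset is already normalized")
  cents <- t(vapply(particles(x), colMeans, numeric(spatialDim(x))))
  centered <- mapply(function(m, i) sweep(m, 2, cents[i, ]),
                     particles(x), seq_along(particles(x)),
                     SIMPLIFY = FALSE)
  s <- max(vapply(centered, function(m) sqrt(max(rowSums(m^2))), 0))
  if (s <= 0)
    stop("degenerate data: zero spread in every particle, ",
         "normalization scale would be 0")
  scaled <- lapply(centered, function(m) m / s)
  particleSet(scaled, ids = particleIds(x), scaleNm = s,
              normalized = TRUE, centroids = cents)
}

#' Invert normalization
#'
#' Multiplies by the stored global scale and re-adds the per-particle
#' centroids, reproducing the original nanometre coordinates.
#'
#' @param x a normalized [ParticleSet-class].
#' @return The un-normalized \code{ParticleSet}.
#' @export
denormalizeParticles <- function(x) {
  stopifnot(is(x, "ParticleSet"))
  if (!isNormalized(x)) stop("dataset is not normalized")
  s <- scaleNm(x)
  parts <- mapply(function(m, i) sweep(m * s, 2, x@centroids[i, ], "+"),
                  particles(x), seq_along(particles(x)),
                  SIMPLIFY = FALSE)
  particleSet(parts, ids = particleIds(x))
}

#' Resample a particle to a fixed number of localizations
#'
#' Uniform sampling with replacement, used to equalize point counts
#' inside a training mini-batch. When \code{nPoints} equals the current
#' count the particle is passed through unchanged. Reproducible for a
#' given \code{seed}.
#'
#' @param points N x p coordinate matrix (one particle).
#' @param nPoints number of rows to return.
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return An \code{nPoints} x p matrix.
#' @export
resampleParticle <- function(points, nPoints, seed = NULL) {
  stopifnot(is.matrix(points), nrow(points) >= 1L)
  if (!is.numeric(nPoints) || length(nPoints) != 1L || nPoints <= 0)
    stop("nPoints must be a positive integer")
  nPoints <- as.integer(nPoints)
  if (nPoints == nrow(points)) return(points)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  points[sample.int(nrow(points), nPoints, replace = TRUE), ,
         drop = FALSE]
}

#' Subsample a fraction of localizations per particle
#'
#' Keeps \code{floor(ratio * N)} (at least 1) localizations per particle,
#' drawn without replacement; used by the missing-data robustness
#' experiment.
#'
#' @param x a [ParticleSet-class].
#' @param ratio fraction in (0, 1].
#' @param seed integer seed.
#' @return A \code{ParticleSet} with reduced localization counts.
#' @export
subsampleLocalizations <- function(x, ratio, seed = NULL) {
  stopifnot(is(x, "ParticleSet"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("ratio must lie in (0, 1]")
  if (ratio == 1) return(x)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  parts <- lapply(particles(x), function(m) {
    k <- max(1L, as.integer(floor(ratio * nrow(m))))
    m[sort(sample.int(nrow(m), k)), , drop = FALSE]
  })
  initialize(x, particles = parts)
}
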