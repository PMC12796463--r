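#' Geometric scaffold models
#'
#' Describes the binding-site scaffold of a simulated structure:
#' \describe{
#'   \item{ring2d}{8 sites equally spaced on a circle (2D NPC
#'     projection); shape parameter: radius.}
#'   \item{double_ring3d}{32 sites in two rings of 16 at z = ±height/2,
#'     the upper ring rotated by half the angular site spacing (3D NPC);
#'     shape parameters: radius and height (ring separation).}
#'   \item{tetrahedron3d}{4 sites: an equilateral base triangle at z = 0
#'     and one apex at z = height above the base centroid (DNA-origami
#'     tetrahedron); shape parameters: height and base edge length.}
#' }
#'
#' @param kind one of \code{"ring2d"}, \code{"double_ring3d"},
#'   \code{"tetrahedron3d"}.
#' @param radiusNm nominal ring radius (ignored by tetrahedron3d).
#' @param heightNm nominal height / ring separation (ignored by ring2d).
#' @param baseEdgeNm tetrahedron base edge length.
#' @return A \code{StructureModel} (S3 list) with fields \code{kind},
#'   \code{nSites}, \code{radiusNm}, \code{heightNm}, \code{baseEdgeNm}.
#' @export
structureModel <- function(kind = c("ring2d", "double_ring3d",
                                    "tetrahedron3d"),
                           radiusNm = 55, heightNm = 48.5,
                           baseEdgeNm = 100) {
  kind <- match.arg(kind)
  nSites <- switch(kind, ring2d = 8L, double_ring3d = 32L,
                   tetrahedron3d = 4L)
  structure(list(kind = kind, nSites = nSites, radiusNm = radiusNm,
                 heightNm = heightNm, baseEdgeNm = baseEdgeNm),
            class = "StructureModel")
}

#' Photophysics of labeling and localization
#'
#' @param dol degree of labeling: probability in (0, 1] that a binding
#'   site carries a fluorophore.
#' @param meanLocsPerSite mean of the number of localization events per
#'   labeled site.
#' @param locPrecisionNm standard deviation (nm, per axis) of the
#'   isotropic Gaussian localization error.
#' @param countLaw law of the per-site localization count:
#'   \code{"poisson"} (zero-truncated Poisson, the default blinking
#'   model) or \code{"fixed"} (exactly \code{round(meanLocsPerSite)}
#'   events per labeled site, useful for exact-geometry checks).
#' @return A \code{PhotophysicsSpec} (S3 list).
#' @export
photophysics <- function(dol = 0.8, meanLocsPerSite = 24,
                         locPrecisionNm = 3,
                         countLaw = c("poisson", "fixed")) {
  if (!(dol > 0 && dol <= 1)) stop("dol must lie in (0, 1]")
  if (meanLocsPerSite <= 0) stop("meanLocsPerSite must be positive")
  if (locPrecisionNm < 0) stop("locPrecisionNm must be >= 0")
  structure(list(dol = dol, meanLocsPerSite = meanLocsPerSite,
                 locPrecisionNm = locPrecisionNm,
                 countLaw = match.arg(countLaw)),
            class = "PhotophysicsSpec")
}

#' Shape-parameter distributions for heterogeneous datasets
#'
#' \code{hetUniform}, \code{hetNormal} and \code{hetFixed} describe the
#' per-particle law of one shape parameter (radius or height, nm).
#' Normal draws are redrawn until positive.
#'
#' @param lo,hi uniform bounds (nm).
#' @param mean,sd normal parameters (nm).
#' @param value fixed value (nm).
#' @return A \code{HetDistribution} (S3 list) with a \code{$sample(n)}
#'   closure.
#' @name hetDistributions
#' @export
hetUniform <- function(lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("require 0 < lo < hi")
  structure(list(kind = "uniform", lo = lo, hi = hi,
                 sample = function(n) stats::runif(n, lo, hi)),
            class = "HetDistribution")
}

#' @rdname hetDistributions
#' @export
hetNormal <- function(mean, sd) {
  if (mean <= 0 || sd < 0) stop("require mean > 0 and sd >= 0")
  structure(list(kind = "normal", mean = mean, sd = sd,
                 sample = function(n) {
                   v <- stats::rnorm(n, mean, sd)
                   while (any(bad <- v <= 0))
                     v[bad] <- stats::rnorm(sum(bad), mean, sd)
                   v
                 }),
            class = "HetDistribution")
}

#' @rdname hetDistributions
#' @export
hetFixed <- function(value) {
  if (value <= 0) stop("require value > 0")
  structure(list(kind = "fixed", value = value,
                 sample = function(n) rep(value, n)),
            class = "HetDistribution")
}

# Site positions (nSites x p, nm) for given shape parameters, centered at
# the scaffold centroid.
scaffoldSites <- function(model, radiusNm = model$radiusNm,
                          heightNm = model$heightNm) {
  switch(model$kind,
    ring2d = {
      a <- 2 * pi * (seq_len(8L) - 1) / 8
      cbind(radiusNm * cos(a), radiusNm * sin(a))
    },
    double_ring3d = {
      a1 <- 2 * pi * (seq_len(16L) - 1) / 16
      a2 <- a1 + pi / 16  # half the angular site spacing
      s <- rbind(cbind(radiusNm * cos(a1), radiusNm * sin(a1),
                       -heightNm / 2),
                 cbind(radiusNm * cos(a2), radiusNm * sin(a2),
                       heightNm / 2))
      s
    },
    tetrahedron3d = {
      rc <- model$baseEdgeNm / sqrt(3)  # base circumradius
      a <- 2 * pi * (0:2) / 3
      s <- rbind(cbind(rc * cos(a), rc * sin(a), 0),
                 c(0, 0, heightNm))
      sweep(s, 2, colMeans(s))  # center at site centroid
    })
}

# z-rotation matrix acting on row vectors (x %*% rotZ(theta, p))
rotZ <- function(theta, p) {
  c2 <- cos(theta); s2 <- sin(theta)
  if (p == 2L) matrix(c(c2, -s2, s2, c2), 2, 2)
  else rbind(c(c2, s2, 0), c(-s2, c2, 0), c(0, 0, 1))
}

#' Simulate one SMLM particle
#'
#' Binding sites of the scaffold are labeled independently with
#' probability \code{dol}; every labeled site emits a zero-truncated
#' Poisson number of localizations, each displaced by isotropic Gaussian
#' localization noise; the whole particle then receives a uniform random
#' rotation about the optical (z) axis — in-plane for 2D. The particle is
#' centered at the scaffold centroid before rotation. If after 100
#' relabeling attempts no site is labeled, an error is raised so dataset
#' sizes stay exact.
#'
#' @param model a [structureModel()].
#' @param phys a [photophysics()] spec.
#' @param radiusNm,heightNm shape parameters for this particle (defaults
#'   taken from \code{model}).
#' @param rotate logical; apply the random rotation (disable for
#'   geometry tests).
#' @return list with \code{points} (N x p matrix, nm),
#'   \code{nLabeledSites}, and \code{rotationRad}.
#' @export
simulateParticle <- function(model, phys, radiusNm = model$radiusNm,
                             heightNm = model$heightNm, rotate = TRUE) {
  sites <- scaffoldSites(model, radiusNm, heightNm)
  p <- ncol(sites)
  labeled <- integer(0)
  for (try in seq_len(100L)) {
    labeled <- which(stats::runif(nrow(sites)) < phys$dol)
    if (length(labeled)) break
  }
  if (!length(labeled))
    stop("degenerate particle: no labeled sites after 100 redraws ",
         "(dol = ", phys$dol, ")")
  counts <- if (identical(phys$countLaw, "fixed")) {
    rep(max(1L, as.integer(round(phys$meanLocsPerSite))),
        length(labeled))
  } else {
    # zero-truncated Poisson counts per labeled site
    vapply(labeled, function(i) {
      k <- stats::rpois(1L, phys$meanLocsPerSite)
      while (k < 1L) k <- stats::rpois(1L, phys$meanLocsPerSite)
      k
    }, 0L)
  }
  pts <- sites[rep(labeled, counts), , drop = FALSE]
  if (phys$locPrecisionNm > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, phys$locPrecisionNm),
                        nrow(pts), p)
  theta <- if (rotate) stats::runif(1, 0, 2 * pi) else 0
  if (theta != 0) pts <- pts %*% rotZ(theta, p)
  list(points = pts, nLabeledSites = length(labeled),
       rotationRad = theta)
}

#' Simulate a heterogeneous particle dataset with ground truth
#'
#' Draws independent shape parameters per particle from the given
#' distributions, simulates every particle with [simulateParticle()], and
#' returns the dataset together with a ground-truth table aligned with
#' dataset order. Fully reproducible for a given seed.
#'
#' @param model a [structureModel()].
#' @param phys a [photophysics()] spec.
#' @param radius,height [hetDistributions] for the shape parameters;
#'   \code{NULL} keeps the model's nominal value fixed.
#' @param nParticles number of particles.
#' @param seed integer RNG seed (\code{NULL}: current stream).
#' @return list with \code{dataset} (a [ParticleSet-class]) and
#'   \code{truth} (data.frame: particle_id, radius_nm, height_nm,
#'   n_localizations, n_labeled_sites).
#' @examples
#' sim <- simulateDataset(structureModel("ring2d"), photophysics(),
#'                        radius = hetUniform(45, 65), nParticles = 5,
#'                        seed = 1)
#' sim$truth$radius_nm
#' @export
simulateDataset <- function(model, phys, radius = NULL, height = NULL,
                            nParticles, seed = NULL) {
  if (nParticles < 1) stop("nParticles must be >= 1")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  radii <- if (is.null(radius)) rep(model$radiusNm, nParticles)
           else radius$sample(nParticles)
  heights <- if (is.null(height)) rep(model$heightNm, nParticles)
             else height$sample(nParticles)
  parts <- vector("list", nParticles)
  nlab <- integer(nParticles)
  for (i in seq_len(nParticles)) {
    sp <- simulateParticle(model, phys, radiusNm = radii[i],
                           heightNm = heights[i])
    parts[[i]] <- sp$points
    nlab[i] <- sp$nLabeledSites
  }
  ds <- particleSet(parts)
  truth <- data.frame(
    particle_id = particleIds(ds),
    radius_nm = radii,
    height_nm = heights,
    n_localizations = nLocalizations(ds),
    n_labeled_sites = nlab)
  list(dataset = ds, truth = truth)
}

#' Dataset presets emulating the three experimental systems
#'
#' Named presets mirroring the descriptive statistics of the three
#' reference datasets: \code{"npc2d"} (8-site ring, radius ~ N(55, 5) nm,
#' about 150 localizations/particle, 3 nm precision), \code{"tetra3d"}
#' (4-site tetrahedron, height ~ U(45, 95) nm, base edge 100 nm,
#' PAINT-like high counts), and \code{"npc3d"} (32 sites in two rings,
#' radius ~ N(55, 2) nm, ring separation ~ N(48.5, 2) nm, about 80
#' localizations/particle). See the package vignette for how the free
#' photophysics values were fixed.
#'
#' @param name preset name.
#' @param nParticles number of particles.
#' @param seed integer seed.
#' @param ... overrides passed to [simulateDataset()] (e.g. a different
#'   \code{radius} distribution).
#' @return As [simulateDataset()].
#' @export
smlmPreset <- function(name = c("npc2d", "tetra3d", "npc3d"),
                       nParticles, seed = NULL, ...) {
  name <- match.arg(name)
  spec <- switch(name,
    npc2d = list(model = structureModel("ring2d", radiusNm = 55),
                 phys = photophysics(dol = 0.8, meanLocsPerSite = 24,
                                     locPrecisionNm = 3),
                 radius = hetNormal(55, 5), height = NULL),
    tetra3d = list(model = structureModel("tetrahedron3d",
                                          heightNm = 70,
                                          baseEdgeNm = 100),
                   phys = photophysics(dol = 0.9,
                                       meanLocsPerSite = 1300,
                                       locPrecisionNm = 3),
                   radius = NULL, height = hetUniform(45, 95)),
    npc3d = list(model = structureModel("double_ring3d", radiusNm = 55,
                                        heightNm = 48.5),
                 phys = photophysics(dol = 0.6, meanLocsPerSite = 4,
                                     locPrecisionNm = 5),
                 radius = hetNormal(55, 2), height = hetNormal(48.5, 2)))
  args <- utils::modifyList(spec, list(...))
  do.call(simulateDataset,
          c(args, list(nParticles = nParticles, seed = seed)))
}
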