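#' Order particles along a latent dimension and bin them
#'
#' Particles are stably sorted by one latent coordinate (ties broken by
#' original index) and partitioned into consecutive equal-count bins of
#' size \code{ceiling(n / nBins)}; the last bin takes the remainder. For
#' 218 particles and 20 bins this gives 19 bins of 11 and a final bin of
#' 9.
#'
#' @param latents n x d matrix of latent coordinates (one row per
#'   particle, typically the encoder means).
#' @param dim latent dimension to order by.
#' @param nBins number of bins (default 20).
#' @return A \code{BinAssignment} (S3 list): \code{order} (particle
#'   indices sorted by the coordinate), \code{bins} (list of index
#'   vectors), \code{binOf} (bin id per particle), \code{dim},
#'   \code{nBins}, \code{boundaries} (per-bin coordinate ranges).
#' @export
orderAndBin <- function(latents, dim = 1L, nBins = 20L) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (n < nBins)
    stop("need at least as many particles (", n, ") as bins (", nBins,
         ")")
  if (dim < 1L || dim > ncol(latents)) stop("latent dim out of range")
  v <- latents[, dim]
  ord <- order(v)                      # stable: ties keep original index
  size <- ceiling(n / nBins)
  binIdx <- pmin(ceiling(seq_len(n) / size), nBins)
  bins <- split(ord, binIdx)
  names(bins) <- NULL
  binOf <- integer(n)
  for (b in seq_along(bins)) binOf[bins[[b]]] <- b
  boundaries <- t(vapply(bins, function(ix) range(v[ix]), numeric(2)))
  colnames(boundaries) <- c("lo", "hi")
  structure(list(order = ord, bins = bins, binOf = binOf,
                 dim = as.integer(dim), nBins = as.integer(nBins),
                 boundaries = boundaries),
            class = "BinAssignment")
}

# rotate rows of an n x p matrix about the z axis
rotatePoints <- function(points, theta) {
  points %*% rotZ(theta, ncol(points))
}

#' Register the particles of one bin into a super-particle
#'
#' The first particle is the reference; each subsequent (centered)
#' particle is rotated about the z axis by the angle minimizing the
#' symmetric Chamfer distance to the growing merged cloud (coarse grid
#' search refined by golden-section search), then merged. All structures
#' handled here have a known symmetry axis normal to the image plane, so
#' in-plane/azimuthal rotation is the only degree of freedom left after
#' centering; the registration interface is pluggable via \code{mode}.
#'
#' @param particleList list of centered N x p coordinate matrices.
#' @param mode \code{"rot_z"} (default) or \code{"none"} (plain union).
#' @param gridDeg angular grid step in degrees for the coarse search.
#' @return A \code{SuperParticle} (S3 list): \code{points} (merged
#'   cloud), \code{memberCount}, \code{rotationsRad}.
#' @export
registerBin <- function(particleList, mode = c("rot_z", "none"),
                        gridDeg = 5) {
  mode <- match.arg(mode)
  if (!length(particleList)) stop("empty bin: nothing to register")
  particleList <- lapply(particleList, as.matrix)
  rots <- numeric(length(particleList))
  merged <- particleList[[1]]
  if (mode == "rot_z" && length(particleList) > 1) {
    grid <- seq(0, 2 * pi, by = gridDeg * pi / 180)
    for (i in 2:length(particleList)) {
      Pm <- particleList[[i]]
      obj <- function(th) chamferDistance(merged, rotatePoints(Pm, th))
      vals <- vapply(grid, obj, 0)
      k <- which.min(vals)
      lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
      opt <- stats::optimize(obj, c(lo, hi))
      best <- if (opt$objective < vals[k]) opt$minimum else grid[k]
      rots[i] <- best
      merged <- rbind(merged, rotatePoints(Pm, best))
    }
  } else if (mode == "none" && length(particleList) > 1) {
    merged <- do.call(rbind, particleList)
  }
  structure(list(points = merged, memberCount = length(particleList),
                 rotationsRad = rots),
            class = "SuperParticle")
}

#' Build super-particles for all bins of one latent dimension
#'
#' @param dataset a [ParticleSet-class] (coordinates in nm; particles
#'   are centered before registration).
#' @param assignment a [orderAndBin()] result.
#' @param mode,gridDeg passed to [registerBin()].
#' @return list of \code{SuperParticle}s, one per bin.
#' @export
superParticles <- function(dataset, assignment,
                           mode = c("rot_z", "none"), gridDeg = 5) {
  stopifnot(is(dataset, "ParticleSet"),
            inherits(assignment, "BinAssignment"))
  mode <- match.arg(mode)
  lapply(assignment$bins, function(ix) {
    centered <- lapply(particles(dataset)[ix], function(m)
      sweep(m, 2, colMeans(m)))
    registerBin(centered, mode = mode, gridDeg = gridDeg)
  })
}

#' Correlate latent coordinates with a reference parameter
#'
#' Pearson product-moment and Spearman rank correlations between each
#' latent dimension and a per-particle parameter vector (estimated or
#' ground-truth radius/height). Zero-variance inputs are flagged
#' undefined rather than reported as numbers.
#'
#' @param latents n x d matrix.
#' @param parameter length-n numeric vector.
#' @return data.frame with columns \code{dim}, \code{pearson},
#'   \code{spearman}, \code{defined}.
#' @export
correlateLatent <- function(latents, parameter) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (length(parameter) != n)
    stop("shape error: parameter length ", length(parameter),
         " does not match ", n, " particles")
  keep <- is.finite(parameter)
  if (!all(keep)) {                 # failed per-particle estimates
    latents <- latents[keep, , drop = FALSE]
    parameter <- parameter[keep]
    n <- nrow(latents)
  }
  if (n < 3) stop("need at least 3 particles to correlate")
  d <- ncol(latents)
  res <- data.frame(dim = seq_len(d), pearson = NA_real_,
                    spearman = NA_real_, defined = FALSE)
  pVar <- stats::var(parameter) > 0
  for (j in seq_len(d)) {
    lj <- latents[, j]
    if (pVar && stats::var(lj) > 0) {
      res$pearson[j] <- stats::cor(lj, parameter)
      res$spearman[j] <- stats::cor(lj, parameter, method = "spearman")
      res$defined[j] <- TRUE
    }
  }
  res
}

#' Robustness of latent-parameter correlation to missing localizations
#'
#' For each sample ratio, a fixed fraction of localizations is kept per
#' particle (drawn without replacement, seeded), the model is retrained
#' from scratch with identical settings, the dataset re-encoded, and the
#' per-dimension correlations against the reference parameter computed.
#'
#' @param dataset an un-normalized [ParticleSet-class] (nm).
#' @param ratios vector of fractions in (0, 1], sorted descending.
#' @param modelCfg a [pcvaeConfig()].
#' @param trainCfg a [trainConfig()]; its seed also seeds the
#'   subsampling.
#' @param referenceParameter length-n vector (ground-truth or estimated
#'   parameter).
#' @return data.frame with columns \code{ratio}, \code{dim},
#'   \code{abs_pearson}, \code{abs_spearman}.
#' @export
robustnessCurve <- function(dataset, ratios, modelCfg, trainCfg,
                            referenceParameter) {
  stopifnot(is(dataset, "ParticleSet"))
  if (any(ratios <= 0 | ratios > 1)) stop("ratios must lie in (0, 1]")
  if (is.unsorted(rev(ratios))) stop("ratios must be sorted descending")
  out <- list()
  for (r in ratios) {
    sub <- subsampleLocalizations(dataset, r,
                                  seed = trainCfg$seed + 7919L)
    norm <- normalizeParticles(sub)
    fit <- trainPCVAE(norm, modelCfg, trainCfg)
    lat <- encodeDataset(fit$model, norm)
    co <- correlateLatent(lat$mu, referenceParameter)
    out[[length(out) + 1L]] <-
      data.frame(ratio = r, dim = co$dim,
                 abs_pearson = abs(co$pearson),
                 abs_spearman = abs(co$spearman))
  }
  do.call(rbind, out)
}
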