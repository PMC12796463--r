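#' @import methods
NULL

#' ParticleSet: a collection of SMLM particles
#'
#' An ordered collection of segmented SMLM particles. Each particle is one
#' copy of a macromolecular structure, represented as an N x p matrix of
#' localization coordinates (p = 2 or 3). Coordinates are in nanometres
#' unless the set has been normalized, in which case every coordinate lies
#' in [-1, 1] and \code{scaleNm} maps normalized units back to nanometres
#' by multiplication (per-particle centroids are kept in \code{centroids}
#' so normalization is invertible).
#'
#' @slot particles list of numeric matrices, one per particle, each N x p.
#' @slot ids character vector of particle identifiers, parallel to
#'   \code{particles}.
#' @slot p integer spatial dimension, 2 or 3.
#' @slot scaleNm positive numeric global scale factor (1 if un-normalized).
#' @slot normalized logical flag.
#' @slot centroids numeric matrix (n_particles x p) of the per-particle
#'   centroids removed during normalization; zero rows if un-normalized.
#'
#' @seealso [particleSet()], [readLocalizations()], [normalizeParticles()]
#' @export
setClass("ParticleSet",
  representation(
    particles  = "list",
    ids        = "character",
    p          = "integer",
    scaleNm    = "numeric",
    normalized = "logical",
    centroids  = "matrix"
  ),
  prototype(
    particles  = list(),
    ids        = character(0),
    p          = 2L,
    scaleNm    = 1,
    normalized = FALSE,
    centroids  = matrix(numeric(0), 0, 2)
  )
)

setValidity("ParticleSet", function(object) {
  msg <- character(0)
  if (!object@p %in% c(2L, 3L))
    msg <- c(msg, "spatial dimension p must be 2 or 3")
  if (length(object@particles) != length(object@ids))
    msg <- c(msg, "particles and ids must have equal length")
  if (length(object@scaleNm) != 1L || !is.finite(object@scaleNm) ||
      object@scaleNm <= 0)
    msg <- c(msg, "scaleNm must be a single positive finite number")
  for (i in seq_along(object@particles)) {
    m <- object@particles[[i]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msg <- c(msg, sprintf("particle %d is not a numeric matrix", i))
      break
    }
    if (nrow(m) < 1L || ncol(m) != object@p) {
      msg <- c(msg, sprintf("particle %d must be N x %d with N >= 1",
                            i, object@p))
      break
    }
    if (!all(is.finite(m))) {
      msg <- c(msg, sprintf("particle %d contains non-finite coordinates", i))
      break
    }
  }
  if (object@normalized && length(object@particles)) {
    rng <- range(vapply(object@particles, function(m) max(abs(m)), 0))
    if (rng[2] > 1 + 1e-9)
      msg <- c(msg, "normalized set has coordinates outside [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ParticleSet
#'
#' @param particles list of N x p numeric matrices (nm).
#' @param ids optional character identifiers; defaults to "1", "2", ...
#' @param scaleNm global normalization scale (nm per normalized unit).
#' @param normalized logical; whether coordinates are already in [-1, 1].
#' @param centroids matrix of removed centroids (used by
#'   [normalizeParticles()]); zero-row matrix if none.
#' @return A [ParticleSet-class] object.
#' @examples
#' ps <- particleSet(list(cbind(c(0, 1), c(0, 0))))
#' length(ps)
#' @export
particleSet <- function(particles, ids = NULL, scaleNm = 1,
                        normalized = FALSE, centroids = NULL) {
  if (!length(particles))
    stop("empty dataset: at least one particle is required")
  particles <- lapply(particles, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  p <- ncol(particles[[1]])
  if (is.null(ids)) ids <- as.character(seq_along(particles))
  if (is.null(centroids))
    centroids <- matrix(0, if (normalized) length(particles) else 0, p)
  new("ParticleSet",
      particles = particles, ids = as.character(ids), p = as.integer(p),
      scaleNm = scaleNm, normalized = normalized, centroids = centroids)
}

#' @describeIn ParticleSet-class compact summary.
#' @param object a \code{ParticleSet}.
#' @export
setMethod("show", "ParticleSet", function(object) {
  n <- length(object@particles)
  nl <- vapply(object@particles, nrow, 0L)
  cat(sprintf("ParticleSet with %d particle%s (p = %d)\n",
              n, if (n == 1) "" else "s", object@p))
  if (n)
    cat(sprintf("  localizations per particle: %d-%d (median %g)\n",
                min(nl), max(nl), stats::median(nl)))
  cat(sprintf("  normalized: %s (scale %.6g nm)\n",
              object@normalized, object@scaleNm))
})

#' @describeIn ParticleSet-class number of particles.
#' @param x a \code{ParticleSet}.
#' @export
setMethod("length", "ParticleSet", function(x) length(x@particles))

#' Subset a ParticleSet
#' @param x a \code{ParticleSet}.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ParticleSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_along(x@particles)[i]
  cents <- if (nrow(x@centroids)) x@centroids[idx, , drop = FALSE]
           else x@centroids
  initialize(x, particles = x@particles[idx], ids = x@ids[idx],
             centroids = cents)
})

#' Extract one particle's coordinate matrix
#' @param x a \code{ParticleSet}.
#' @param i single index or id.
#' @export
setMethod("[[", "ParticleSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  x@particles[[i]]
})

#' @rdname particleAccessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname particleAccessors
#' @export
setGeneric("particleIds", function(x) standardGeneric("particleIds"))
#' @rdname particleAccessors
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))
#' @rdname particleAccessors
#' @export
setGeneric("scaleNm", function(x) standardGeneric("scaleNm"))
#' @rdname particleAccessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname particleAccessors
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' Accessors for ParticleSet
#'
#' \code{particles} returns the list of coordinate matrices;
#' \code{particleIds} the identifiers; \code{spatialDim} the spatial
#' dimension p; \code{scaleNm} the global nm scale; \code{isNormalized}
#' the normalization flag; \code{nLocalizations} the per-particle
#' localization counts.
#'
#' @param x a [ParticleSet-class].
#' @name particleAccessors
NULL

#' @rdname particleAccessors
#' @export
setMethod("particles", "ParticleSet", function(x) x@particles)
#' @rdname particleAccessors
#' @export
setMethod("particleIds", "ParticleSet", function(x) x@ids)
#' @rdname particleAccessors
#' @export
setMethod("spatialDim", "ParticleSet", function(x) x@p)
#' @rdname particleAccessors
#' @export
setMethod("scaleNm", "ParticleSet", function(x) x@scaleNm)
#' @rdname particleAccessors
#' @export
setMethod("isNormalized", "ParticleSet", function(x) x@normalized)
#' @rdname particleAccessors
#' @export
setMethod("nLocalizations", "ParticleSet", function(x)
  vapply(x@particles, nrow, 0L))
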