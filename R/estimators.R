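#' Model-based geometric parameter estimators
#'
#' Independent, latent-free estimates of ring radius and structure height
#' used to validate latent-space orderings. All estimators are invariant
#' to translation and to rotation about the optical (z) axis. Each
#' returns a \code{ParameterEstimate}: a list with \code{value} (nm),
#' \code{precision} (nm, a standard error derived from the full width at
#' half maximum of the underlying histogram divided by the square root of
#' the number of localizations), \code{nLocalizations} and \code{method}.
#'
#' @details
#' \code{estimateRadius2D}: localizations are centered by subtracting the
#' mean localization, transformed to polar coordinates, and the mean
#' radial coordinate is the radius estimate. For a ring of radius R
#' blurred by isotropic Gaussian noise of s.d. \eqn{\sigma} the mean
#' radial coordinate is biased upward by approximately
#' \eqn{\sigma^2 / (2R)}.
#'
#' \code{estimateRadius3D}: centered as in 2D; the median of the
#' cylindrical radial coordinate (from x, y only) is used, which is
#' robust to axial outliers.
#'
#' \code{estimateHeightNPC3D}: localizations are projected on z; the
#' central plane is the mean z; the height is the difference between the
#' median of points above and the median of points below that plane.
#'
#' \code{estimateHeightTetrahedron}: a two-component Gaussian mixture is
#' fitted to the z-coordinates by expectation-maximization (components
#' for the 3-site base plate and the apex); the height is the absolute
#' difference of the fitted means.
#'
#' @param points N x p numeric matrix of localization coordinates (nm).
#' @return A \code{ParameterEstimate} list.
#' @name paramEstimators
NULL

newEstimate <- function(value, values, method) {
  list(value = value, precision = estimatePrecision(values),
       nLocalizations = length(values), method = method)
}

#' @rdname paramEstimators
#' @export
estimateRadius2D <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L)
  if (nrow(points) < 2L)
    stop("insufficient data: at least 2 localizations required")
  ctr <- sweep(points, 2, colMeans(points))
  r <- sqrt(rowSums(ctr^2))
  newEstimate(mean(r), r, "radius2d_radial_mean")
}

#' @rdname paramEstimators
#' @export
estimateRadius3D <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  if (nrow(points) < 2L)
    stop("insufficient data: at least 2 localizations required")
  ctr <- sweep(points, 2, colMeans(points))
  r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  newEstimate(stats::median(r), r, "radius3d_radial_median")
}

#' @rdname paramEstimators
#' @export
estimateHeightNPC3D <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  z <- points[, 3]
  mid <- mean(z)
  up <- z[z > mid]; lo <- z[z < mid]
  if (!length(up) || !length(lo))
    stop("degenerate geometry: all localizations on one side of the ",
         "central plane")
  newEstimate(stats::median(up) - stats::median(lo), z,
              "height3d_median_split")
}

#' @rdname paramEstimators
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @export
estimateHeightTetrahedron <- function(points, maxIter = 500L,
                                      tol = 1e-8) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  if (nrow(points) < 10L)
    stop("insufficient data: at least 10 localizations required")
  z <- points[, 3]
  if (stats::sd(z) == 0) stop("degenerate geometry: zero z spread")
  fit <- gaussianMixture2(z, maxIter = maxIter, tol = tol)
  est <- newEstimate(abs(fit$mu[2] - fit$mu[1]), z,
                     "height_tetrahedron_gmm")
  est$mixture <- fit
  est
}

# Two-component univariate Gaussian mixture by EM.
# Means initialized at the 25th/75th percentiles; variance floor 1e-6
# keeps well-separated noiseless components from collapsing.
gaussianMixture2 <- function(x, maxIter = 500L, tol = 1e-8) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  s2 <- rep(max(stats::var(x) / 4, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- cbind(w[1] * stats::dnorm(x, mu[1], sqrt(s2[1])),
                  w[2] * stats::dnorm(x, mu[2], sqrt(s2[2])))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      return(list(mu = mu, sigma = sqrt(s2), weight = w,
                  logLik = ll, iterations = it, converged = TRUE))
    }
    ll_old <- ll
  }
  stop("EM did not converge within ", maxIter, " iterations")
}

#' FWHM-based precision of a parameter estimate
#'
#' The full width at half maximum of the sample's histogram is computed
#' bin-free as \eqn{2\sqrt{2\ln 2}} times a robust Gaussian sigma (1.4826
#' times the median absolute deviation); the returned standard error is
#' FWHM divided by \eqn{\sqrt{N}}.
#'
#' @param values numeric sample (length >= 2; a constant sample gives 0).
#' @return Standard error in the units of \code{values}.
#' @export
estimatePrecision <- function(values) {
  if (length(values) < 2L)
    stop("insufficient data: at least 2 values required")
  sig <- stats::mad(values)  # 1.4826 * MAD, consistent for a Gaussian
  fwhm <- 2 * sqrt(2 * log(2)) * sig
  fwhm / sqrt(length(values))
}

#' Apply an estimator to every particle of a dataset
#'
#' @param x a [ParticleSet-class] (un-normalized, nm).
#' @param method one of \code{"npc2d"} (radial mean),
#'   \code{"npc3d-radius"}, \code{"npc3d-height"}, \code{"tetra"}.
#' @return data.frame with columns particle_id, value_nm, precision_nm,
#'   n_locs.
#' @export
estimateParameters <- function(x, method = c("npc2d", "npc3d-radius",
                                             "npc3d-height", "tetra")) {
  stopifnot(is(x, "ParticleSet"))
  method <- match.arg(method)
  fn <- switch(method,
               "npc2d" = estimateRadius2D,
               "npc3d-radius" = estimateRadius3D,
               "npc3d-height" = estimateHeightNPC3D,
               "tetra" = estimateHeightTetrahedron)
  res <- lapply(particles(x), function(m)
    tryCatch(fn(m), error = function(e)
      list(value = NA_real_, precision = NA_real_,
           nLocalizations = nrow(m))))
  nFail <- sum(vapply(res, function(r) is.na(r$value), NA))
  if (nFail)
    warning(nFail, " particle(s) could not be estimated (NA returned)")
  data.frame(particle_id = particleIds(x),
             value_nm = vapply(res, `[[`, 0, "value"),
             precision_nm = vapply(res, `[[`, 0, "precision"),
             n_locs = vapply(res, function(r)
               as.integer(r$nLocalizations), 0L))
}
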