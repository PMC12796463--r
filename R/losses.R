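#' Loss configuration
#'
#' @param betaMax peak balancing coefficient multiplying the KLD term.
#'   The default keeps latent regularization subdominant to the Chamfer
#'   term on [-1, 1]-normalized coordinates.
#' @param warmupSteps length of the sigmoid warm-up of the KLD weight
#'   (optimization steps).
#' @return A \code{LossConfig} (S3 list).
#' @export
lossConfig <- function(betaMax = 1e-3, warmupSteps = 5000L) {
  if (betaMax < 0) stop("betaMax must be >= 0")
  if (warmupSteps < 0) stop("warmupSteps must be >= 0")
  structure(list(betaMax = betaMax,
                 warmupSteps = as.integer(warmupSteps)),
            class = "LossConfig")
}

#' Symmetric Chamfer distance between two point sets
#'
#' \deqn{\mathrm{CD}(X, \hat X) = \frac{1}{N}\Big(\sum_{x \in X}
#'   \min_{\hat x} \lVert x - \hat x \rVert_2^2 +
#'   \sum_{\hat x \in \hat X} \min_{x} \lVert x - \hat x \rVert_2^2\Big)}
#' with \eqn{N = |X|}. Symmetric in content, but normalized by the size
#' of the first set. Used as the permutation-invariant reconstruction
#' loss.
#'
#' @param X N x p matrix.
#' @param Xhat Nhat x p matrix.
#' @return Nonnegative scalar; 0 iff the two sets are equal as sets.
#' @examples
#' chamferDistance(rbind(c(0, 0)), rbind(c(3, 4)))         # 50
#' chamferDistance(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0)))  # 0.5
#' @export
chamferDistance <- function(X, Xhat) {
  cd <- chamferParts(X, Xhat)
  cd$value
}

# squared-distance matrix, nearest neighbours both ways, and the loss;
# also used for the analytic gradient during training
chamferParts <- function(X, Xhat) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Xhat)) Xhat <- as.matrix(Xhat)
  if (!nrow(X) || !nrow(Xhat))
    stop("Chamfer distance requires two non-empty point sets")
  if (ncol(X) != ncol(Xhat))
    stop("point sets must share the spatial dimension")
  n <- nrow(X)
  D <- outer(rowSums(X^2), rowSums(Xhat^2), "+") - 2 * tcrossprod(X, Xhat)
  D[D < 0] <- 0                      # numerical floor
  j1 <- max.col(-D, ties.method = "first")       # nn of each x in Xhat
  i2 <- max.col(-t(D), ties.method = "first")    # nn of each xhat in X
  v1 <- D[cbind(seq_len(n), j1)]
  v2 <- D[cbind(i2, seq_len(nrow(Xhat)))]
  list(value = (sum(v1) + sum(v2)) / n, j1 = j1, i2 = i2, n = n)
}

# gradient of chamferDistance with respect to Xhat
chamferGradXhat <- function(X, Xhat, parts = NULL) {
  if (is.null(parts)) parts <- chamferParts(X, Xhat)
  n <- parts$n
  dXhat <- 2 * (Xhat - X[parts$i2, , drop = FALSE]) / n
  diff1 <- 2 * (Xhat[parts$j1, , drop = FALSE] - X) / n
  acc <- rowsum(diff1, parts$j1, reorder = FALSE)
  dXhat[as.integer(rownames(acc)), ] <-
    dXhat[as.integer(rownames(acc)), , drop = FALSE] + acc
  dXhat
}

#' Kullback-Leibler divergence to the standard normal prior
#'
#' Closed form for a diagonal Gaussian posterior
#' \eqn{\mathcal N(\mu, \mathrm{diag}(\sigma^2))} against
#' \eqn{\mathcal N(0, I)}:
#' \deqn{\tfrac12 \sum_i (\mu_i^2 + \sigma_i^2 - \log \sigma_i^2 - 1).}
#'
#' @param mu,sigma numeric vectors of equal length; \code{sigma > 0}.
#' @return Nonnegative scalar.
#' @examples
#' kldGaussian(0, 1)     # 0
#' kldGaussian(1, 1)     # 0.5
#' @export
kldGaussian <- function(mu, sigma) {
  if (length(mu) != length(sigma)) stop("mu and sigma lengths differ")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  0.5 * sum(mu^2 + sigma^2 - log(sigma^2) - 1)
}

#' Sigmoid warm-up schedule for the KLD weight
#'
#' \eqn{\beta(t) = \beta_{\max} \,
#' \mathrm{logistic}\!\big(k (t - T/2)/T\big)} with steepness
#' \eqn{k = 12} and warm-up length \eqn{T}: monotone nondecreasing,
#' at most 1\% of \eqn{\beta_{\max}} at step 0, at least 99\% at step
#' \eqn{T}, and \eqn{\beta_{\max}/2} at the midpoint. With \eqn{T = 0}
#' the weight is constantly \eqn{\beta_{\max}}.
#'
#' @param step optimization step (0-based), vectorized.
#' @param cfg a [lossConfig()].
#' @return Numeric vector of KLD weights.
#' @export
betaSchedule <- function(step, cfg = lossConfig()) {
  Tw <- cfg$warmupSteps
  if (Tw == 0) return(rep(cfg$betaMax, length(step)))
  k <- 12
  cfg$betaMax * stats::plogis(k * (step - Tw / 2) / Tw)
}

#' Total PC-VAE loss for one particle
#'
#' Chamfer reconstruction term plus the warm-up-weighted KLD:
#' \code{chamferDistance(X, Xhat) + betaSchedule(step, cfg) *
#' kldGaussian(mu, sigma)}. During training this quantity is averaged
#' over the particles of a mini-batch.
#'
#' @param X,Xhat input and reconstructed point sets.
#' @param mu,sigma latent Gaussian parameters.
#' @param step optimization step (determines the KLD weight).
#' @param cfg a [lossConfig()].
#' @return list with \code{total}, \code{chamfer}, \code{kld},
#'   \code{beta}.
#' @export
totalLoss <- function(X, Xhat, mu, sigma, step = 0L,
                      cfg = lossConfig()) {
  ch <- chamferDistance(X, Xhat)
  kl <- kldGaussian(mu, sigma)
  b <- betaSchedule(step, cfg)
  list(total = ch + b * kl, chamfer = ch, kld = kl, beta = b)
}
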