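#' Training configuration
#'
#' Optimizer and batching hyperparameters. Defaults follow the published
#' recipe: Adam with initial learning rate 1e-4 and weight decay 1e-5,
#' mini-batches of M = 8 particles, 4 epochs, and a sigmoid KLD warm-up
#' over the first 5000 optimization steps.
#'
#' @param batchSize mini-batch size M.
#' @param epochs number of passes over the dataset.
#' @param learningRate Adam step size.
#' @param weightDecay L2 coefficient added to the gradient.
#' @param seed integer seed governing initialization, shuffling,
#'   per-batch resampling and latent draws.
#' @param loss a [lossConfig()].
#' @param resamplePoints points per particle inside a training batch
#'   (default 256). Decoupled from the decoder's \code{nOutputPoints}:
#'   feeding the encoder more input points reduces the sampling noise of
#'   its mean-pooled feature, while the Chamfer loss accepts unequal set
#'   sizes.
#' @return A \code{TrainConfig} (S3 list).
#' @export
trainConfig <- function(batchSize = 8L, epochs = 4L,
                        learningRate = 1e-4, weightDecay = 1e-5,
                        seed = 1L, loss = lossConfig(),
                        resamplePoints = 256L) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 weightDecay = weightDecay, seed = as.integer(seed),
                 loss = loss, resamplePoints = resamplePoints),
            class = "TrainConfig")
}

# one training step: forward in training mode, mean loss over the batch,
# analytic gradients for every parameter. Xlist: list of n x p matrices
# (equal n); eps: B x d standard-normal draws.
batchForwardBackward <- function(cfg, params, running, Xlist, eps,
                                 beta) {
  B <- length(Xlist)
  n <- nrow(Xlist[[1]])
  X <- do.call(rbind, Xlist)
  group <- rep(seq_len(B), each = n)
  ef <- encFwd(cfg, params, running, X, group, B, training = TRUE)
  mu <- ef$mu; lv <- ef$lv
  sigma <- exp(0.5 * lv)
  Z <- mu + sigma * eps
  df <- decFwd(cfg, params, running, Z, training = TRUE)
  Ns <- cfg$nOutputPoints
  cham <- numeric(B)
  dXhat <- matrix(0, B * Ns, cfg$p)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * Ns + 1):(b * Ns)
    Xh <- df$Xhat[rows, , drop = FALSE]
    parts <- chamferParts(Xlist[[b]], Xh)
    cham[b] <- parts$value
    dXhat[rows, ] <- chamferGradXhat(Xlist[[b]], Xh, parts) / B
  }
  kld <- 0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
  db <- decBwd(cfg, params, Z, df, dXhat)
  dZ <- db$dZ
  dmu <- dZ + beta * mu / B
  dlv <- dZ * (0.5 * sigma * eps) + beta * 0.5 * (exp(lv) - 1) / B
  eg <- encBwd(cfg, params, ef, dmu, dlv)
  grads <- c(db$grads, eg)
  newRun <- c(ef$newRun, df$newRun)
  list(chamfer = mean(cham), kld = mean(kld),
       total = mean(cham) + beta * mean(kld),
       grads = grads, newRun = newRun)
}

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, state, lr, wd,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gphi <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gphi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gphi^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a PC-VAE on a normalized particle dataset
#'
#' Per epoch the particles are shuffled (seeded) and partitioned into
#' mini-batches of M (the last batch may be smaller and is kept). Every
#' particle in a batch is resampled with replacement to a common point
#' count so point clouds stack into a batch; inference later uses the
#' full point sets. Adam updates use the configured learning rate and
#' weight decay; the KLD weight follows [betaSchedule()] on the global
#' step counter. All randomness (initialization, shuffling, resampling,
#' latent draws) derives from \code{trainCfg$seed}, so runs are exactly
#' reproducible.
#'
#' @param dataset a normalized [ParticleSet-class].
#' @param modelCfg a [pcvaeConfig()]; its \code{p} must match the data.
#' @param trainCfg a [trainConfig()].
#' @param model optional pre-initialized [PCVAE-class] to continue
#'   training.
#' @param verbose print a line per epoch.
#' @return list with \code{model} (the trained [PCVAE-class]) and
#'   \code{history} (data.frame: step, epoch, loss_total, loss_chamfer,
#'   loss_kld, beta).
#' @export
trainPCVAE <- function(dataset, modelCfg, trainCfg = trainConfig(),
                       model = NULL, verbose = FALSE) {
  stopifnot(is(dataset, "ParticleSet"))
  if (!isNormalized(dataset))
    stop("dataset must be normalized (see normalizeParticles)")
  if (spatialDim(dataset) != modelCfg$p)
    stop("model p = ", modelCfg$p, " does not match dataset p = ",
         spatialDim(dataset))
  nPart <- length(dataset)
  M <- trainCfg$batchSize
  if (nPart < M)
    stop("dataset has fewer particles (", nPart,
         ") than the batch size (", M, ")")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(trainCfg$seed)
  if (is.null(model)) model <- pcvae(modelCfg)
  env <- model@env
  nRes <- if (is.null(trainCfg$resamplePoints)) modelCfg$nOutputPoints
          else as.integer(trainCfg$resamplePoints)
  adam <- adamInit(env$params)
  parts <- particles(dataset)
  hist <- list()
  step <- 0L
  for (epoch in seq_len(trainCfg$epochs)) {
    ord <- sample.int(nPart)
    batches <- split(ord, ceiling(seq_along(ord) / M))
    for (bt in batches) {
      Xlist <- lapply(parts[bt], function(m)
        if (nrow(m) == nRes) m
        else m[sample.int(nrow(m), nRes, replace = TRUE), ,
               drop = FALSE])
      eps <- matrix(stats::rnorm(length(bt) * modelCfg$d),
                    length(bt), modelCfg$d)
      beta <- betaSchedule(step, trainCfg$loss)
      fb <- batchForwardBackward(modelCfg, env$params, env$running,
                                 Xlist, eps, beta)
      if (!is.finite(fb$total))
        stop("training diverged: non-finite loss at step ", step)
      up <- adamStep(env$params, fb$grads, adam,
                     trainCfg$learningRate, trainCfg$weightDecay)
      env$params <- up$params
      adam <- up$state
      for (nm in names(fb$newRun)) env$running[[nm]] <- fb$newRun[[nm]]
      step <- step + 1L
      hist[[step]] <- c(step = step, epoch = epoch,
                        loss_total = fb$total,
                        loss_chamfer = fb$chamfer, loss_kld = fb$kld,
                        beta = beta)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  chamfer %.5f  kld %.3f", epoch,
                      trainCfg$epochs, fb$chamfer, fb$kld))
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(model = model, history = history)
}

#' Encode every particle of a dataset into latent space
#'
#' Evaluation-mode encoding of all particles using all their
#' localizations (no resampling at inference). Because evaluation-mode
#' batch-norm is a fixed per-channel affine map, all points are pushed
#' through the shared per-point layers in one matrix operation and then
#' mean-pooled per particle; the result is identical to encoding
#' particles one at a time.
#'
#' @param model a trained [PCVAE-class].
#' @param dataset a normalized [ParticleSet-class].
#' @return list with \code{mu} and \code{sigma}, both n_particles x d
#'   matrices (rows follow dataset order).
#' @export
encodeDataset <- function(model, dataset) {
  stopifnot(is(model, "PCVAE"), is(dataset, "ParticleSet"))
  cfg <- model@config
  if (spatialDim(dataset) != cfg$p)
    stop("shape error: dataset p = ", spatialDim(dataset),
         " but model expects p = ", cfg$p)
  parts <- particles(dataset)
  n <- vapply(parts, nrow, 0L)
  # chunk over particles so intermediate feature matrices stay small
  # (PAINT-scale datasets can exceed a million localizations)
  chunkRows <- 20000L
  chunk <- cumsum(n) %/% chunkRows
  idxChunks <- split(seq_along(parts), chunk)
  mu <- matrix(0, length(parts), cfg$d)
  lv <- matrix(0, length(parts), cfg$d)
  for (ic in idxChunks) {
    X <- do.call(rbind, parts[ic])
    group <- rep(seq_along(ic), n[ic])
    fw <- encFwd(cfg, model@env$params, model@env$running, X, group,
                 length(ic), training = FALSE)
    mu[ic, ] <- fw$mu
    lv[ic, ] <- fw$lv
  }
  list(mu = mu, sigma = exp(0.5 * lv))
}
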