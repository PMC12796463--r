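#' PC-VAE architecture configuration
#'
#' Hyperparameters of the point-cloud variational auto-encoder. The
#' encoder applies three shared-weight per-point MLP layers (batch-norm +
#' ReLU) and mean-pools over points; two separate MLP heads map the
#' pooled feature to the latent mean and log-variance. The decoder
#' expands a latent draw through three fully connected Tanh/batch-norm
#' layers with an additive linear skip connection from the latent vector
#' at the widest layer, tiles the global feature over
#' \code{nOutputPoints} positions (concatenating a learned per-index
#' embedding), applies two kernel-size-1 convolutions and 4-head
#' self-attention over the point axis, and maps to p coordinates with a
#' bounded Tanh output.
#'
#' @param p input spatial dimension, 2 or 3.
#' @param d latent dimension (default 8).
#' @param encoderWidths per-point MLP output widths.
#' @param headWidth hidden width of the latent mean / log-variance heads.
#' @param decoderWidths fully connected expansion widths.
#' @param nHeads number of self-attention heads; must divide the last
#'   decoder width.
#' @param nOutputPoints number of reconstructed points N_s (decoupled
#'   from the input localization count; the Chamfer loss tolerates
#'   unequal set sizes).
#' @param indexEmbedDim width of the learned per-index embedding used to
#'   expand one global feature vector into a point sequence.
#' @return A \code{ModelConfig} (S3 list).
#' @export
pcvaeConfig <- function(p, d = 8L, encoderWidths = c(64L, 128L, 1024L),
                        headWidth = 512L,
                        decoderWidths = c(256L, 512L, 1024L),
                        nHeads = 4L, nOutputPoints = 64L,
                        indexEmbedDim = 32L) {
  if (!p %in% c(2L, 3L)) stop("p must be 2 or 3")
  if (d < 1L) stop("latent dimension d must be >= 1")
  if (any(c(encoderWidths, headWidth, decoderWidths, nOutputPoints,
            indexEmbedDim) < 1))
    stop("all widths must be positive")
  C <- decoderWidths[length(decoderWidths)]
  if (C %% nHeads != 0)
    stop("nHeads must divide the attention channel width ", C)
  structure(list(p = as.integer(p), d = as.integer(d),
                 encoderWidths = as.integer(encoderWidths),
                 headWidth = as.integer(headWidth),
                 decoderWidths = as.integer(decoderWidths),
                 nHeads = as.integer(nHeads),
                 nOutputPoints = as.integer(nOutputPoints),
                 indexEmbedDim = as.integer(indexEmbedDim)),
            class = "ModelConfig")
}

#' PCVAE: the point-cloud variational auto-encoder
#'
#' Holds the architecture configuration and all learnable parameters
#' (encoder \eqn{\phi}, decoder \eqn{\theta}) plus batch-norm running
#' statistics. Parameters live in an environment, so training updates the
#' model by reference; [trainPCVAE()] also returns it for pipeline style.
#'
#' @slot config a [pcvaeConfig()] list.
#' @slot env environment with \code{params} (named list of numeric
#'   arrays) and \code{running} (batch-norm running means/variances).
#' @seealso [pcvae()], [encodeParticle()], [decodeLatent()]
#' @export
setOldClass("ModelConfig")
setClass("PCVAE",
         representation(config = "ModelConfig", env = "environment"))

setValidity("PCVAE", function(object) {
  if (!is.list(object@env$params) || !length(object@env$params))
    return("model has no parameters")
  TRUE
})

#' @describeIn PCVAE-class compact summary.
#' @param object a \code{PCVAE}.
#' @export
setMethod("show", "PCVAE", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@env$params, length, 0L))
  cat(sprintf("PCVAE (p = %d, d = %d)\n", cfg$p, cfg$d))
  cat(sprintf("  encoder widths: %s; heads: 2 x (%d -> %d -> %d)\n",
              paste(cfg$encoderWidths, collapse = "/"),
              cfg$encoderWidths[3], cfg$headWidth, cfg$d))
  cat(sprintf("  decoder widths: %s + skip; %d-head attention; N_s = %d\n",
              paste(cfg$decoderWidths, collapse = "/"), cfg$nHeads,
              cfg$nOutputPoints))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
})

#' Construct and initialize a PC-VAE
#'
#' Weights and biases use uniform fan-in initialization; batch-norm
#' scales start at 1 with running mean 0 / variance 1, so a freshly
#' initialized model in evaluation mode applies near-identity
#' normalization.
#'
#' @param config a [pcvaeConfig()].
#' @param seed optional integer seed for reproducible initialization.
#' @return A [PCVAE-class] object.
#' @examples
#' m <- pcvae(pcvaeConfig(p = 2, nOutputPoints = 16), seed = 1)
#' m
#' @export
pcvae <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ModelConfig"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  ew <- config$encoderWidths; dw <- config$decoderWidths
  d <- config$d; C <- dw[length(dw)]
  p <- list(); r <- list()
  addLin <- function(nm, fi, fo) {
    l <- initLinear(fi, fo)
    p[[paste0(nm, "W")]] <<- l$W
    p[[paste0(nm, "b")]] <<- l$b
  }
  addBN <- function(nm, C) {
    p[[paste0(nm, "G")]] <<- rep(1, C)
    p[[paste0(nm, "B")]] <<- rep(0, C)
    r[[paste0(nm, "M")]] <<- rep(0, C)
    r[[paste0(nm, "V")]] <<- rep(1, C)
  }
  # encoder: shared per-point MLPs
  fi <- config$p
  for (i in seq_along(ew)) {
    addLin(paste0("enc", i), fi, ew[i]); addBN(paste0("ebn", i), ew[i])
    fi <- ew[i]
  }
  addLin("mu1", ew[3], config$headWidth)
  addLin("mu2", config$headWidth, d)
  addLin("lv1", ew[3], config$headWidth)
  addLin("lv2", config$headWidth, d)
  # start with a small posterior sigma (~exp(-2)) so the short training
  # schedule is reconstruction-driven from the first step; with sigma
  # near 1 the decoder input is dominated by the latent noise draw
  p$lv2b <- rep(-4, d)
  # decoder: FC expansion + skip
  fi <- d
  for (i in seq_along(dw)) {
    addLin(paste0("dec", i), fi, dw[i]); addBN(paste0("dbn", i), dw[i])
    fi <- dw[i]
  }
  p$skipW <- initLinear(d, C)$W
  p$emb <- matrix(stats::rnorm(config$nOutputPoints *
                                 config$indexEmbedDim),
                  config$nOutputPoints, config$indexEmbedDim)
  addLin("conv1", C + config$indexEmbedDim, C); addBN("cbn1", C)
  addLin("conv2", C, C); addBN("cbn2", C)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    l <- initLinear(C, C)
    p[[nm]] <- l$W
    p[[sub("W", "b", nm)]] <- l$b
  }
  addLin("out", C, config$p)
  env <- new.env(parent = emptyenv())
  env$params <- p
  env$running <- r
  new("PCVAE", config = config, env = env)
}

# ---- encoder forward (eval + train) -------------------------------------

# X: R x p matrix of all points; group: length-R integer particle index
# (1..B). Returns mu, lv (B x d). In training mode batch statistics are
# used and caches + running-stat updates are returned.
encFwd <- function(cfg, params, running, X, group, B, training = FALSE) {
  caches <- list(); newRun <- list()
  H <- X
  for (i in 1:3) {
    li <- paste0("enc", i); bi <- paste0("ebn", i)
    Z <- linFwd(H, params[[paste0(li, "W")]], params[[paste0(li, "b")]])
    if (training) {
      bn <- bnFwdTrain(Z, params[[paste0(bi, "G")]],
                       params[[paste0(bi, "B")]])
      A <- bn$Y
      newRun[[paste0(bi, "M")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "M")]] +
        BN_MOMENTUM * bn$batchMean
      newRun[[paste0(bi, "V")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "V")]] +
        BN_MOMENTUM * bn$batchVarUnbiased
      caches[[bi]] <- bn$cache
    } else {
      A <- bnFwdEval(Z, params[[paste0(bi, "G")]],
                     params[[paste0(bi, "B")]],
                     running[[paste0(bi, "M")]],
                     running[[paste0(bi, "V")]])
    }
    Y <- reluFwd(A)
    caches[[paste0("h", i, "in")]] <- H
    caches[[paste0("h", i, "out")]] <- Y
    H <- Y
  }
  cnt <- tabulate(group, B)
  G <- rowsum(H, group, reorder = TRUE) / cnt
  M1 <- reluFwd(linFwd(G, params$mu1W, params$mu1b))
  mu <- linFwd(M1, params$mu2W, params$mu2b)
  L1 <- reluFwd(linFwd(G, params$lv1W, params$lv1b))
  lv <- linFwd(L1, params$lv2W, params$lv2b)
  list(mu = mu, lv = lv, G = G, M1 = M1, L1 = L1, caches = caches,
       newRun = newRun, group = group, cnt = cnt)
}

encBwd <- function(cfg, params, fw, dmu, dlv) {
  g <- list()
  lb <- linBwd(dmu, fw$M1, params$mu2W)
  g$mu2W <- lb$dW; g$mu2b <- lb$db
  dM1 <- reluBwd(lb$dX, fw$M1)
  lb <- linBwd(dM1, fw$G, params$mu1W)
  g$mu1W <- lb$dW; g$mu1b <- lb$db
  dG <- lb$dX
  lb <- linBwd(dlv, fw$L1, params$lv2W)
  g$lv2W <- lb$dW; g$lv2b <- lb$db
  dL1 <- reluBwd(lb$dX, fw$L1)
  lb <- linBwd(dL1, fw$G, params$lv1W)
  g$lv1W <- lb$dW; g$lv1b <- lb$db
  dG <- dG + lb$dX
  # mean-pool backward
  dH <- (dG / fw$cnt)[fw$group, , drop = FALSE]
  for (i in 3:1) {
    bi <- paste0("ebn", i); li <- paste0("enc", i)
    dA <- reluBwd(dH, fw$caches[[paste0("h", i, "out")]])
    bb <- bnBwd(dA, fw$caches[[bi]])
    g[[paste0(bi, "G")]] <- bb$dgamma
    g[[paste0(bi, "B")]] <- bb$dbeta
    lb <- linBwd(bb$dX, fw$caches[[paste0("h", i, "in")]],
                 params[[paste0(li, "W")]])
    g[[paste0(li, "W")]] <- lb$dW
    g[[paste0(li, "b")]] <- lb$db
    dH <- lb$dX
  }
  g
}

# ---- decoder forward (eval + train) -------------------------------------

decFwd <- function(cfg, params, running, Z, training = FALSE) {
  B <- nrow(Z); Ns <- cfg$nOutputPoints
  C <- cfg$decoderWidths[length(cfg$decoderWidths)]
  caches <- list(); newRun <- list()
  H <- Z
  for (i in 1:3) {
    li <- paste0("dec", i); bi <- paste0("dbn", i)
    Zi <- linFwd(H, params[[paste0(li, "W")]], params[[paste0(li, "b")]])
    if (training) {
      bn <- bnFwdTrain(Zi, params[[paste0(bi, "G")]],
                       params[[paste0(bi, "B")]])
      A <- bn$Y
      newRun[[paste0(bi, "M")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "M")]] +
        BN_MOMENTUM * bn$batchMean
      newRun[[paste0(bi, "V")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "V")]] +
        BN_MOMENTUM * bn$batchVarUnbiased
      caches[[bi]] <- bn$cache
    } else {
      A <- bnFwdEval(Zi, params[[paste0(bi, "G")]],
                     params[[paste0(bi, "B")]],
                     running[[paste0(bi, "M")]],
                     running[[paste0(bi, "V")]])
    }
    Y <- tanhFwd(A)
    caches[[paste0("f", i, "in")]] <- H
    caches[[paste0("f", i, "out")]] <- Y
    H <- Y
  }
  G <- H + Z %*% params$skipW        # skip connection at the widest layer
  # expand one global vector into a point sequence
  gidx <- rep(seq_len(B), each = Ns)
  eidx <- rep(seq_len(Ns), times = B)
  H0 <- cbind(G[gidx, , drop = FALSE], params$emb[eidx, , drop = FALSE])
  caches$gidx <- gidx; caches$eidx <- eidx; caches$H0 <- H0
  for (i in 1:2) {
    li <- paste0("conv", i); bi <- paste0("cbn", i)
    Zi <- linFwd(if (i == 1) H0 else caches$c1out,
                 params[[paste0(li, "W")]], params[[paste0(li, "b")]])
    if (training) {
      bn <- bnFwdTrain(Zi, params[[paste0(bi, "G")]],
                       params[[paste0(bi, "B")]])
      A <- bn$Y
      newRun[[paste0(bi, "M")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "M")]] +
        BN_MOMENTUM * bn$batchMean
      newRun[[paste0(bi, "V")]] <-
        (1 - BN_MOMENTUM) * running[[paste0(bi, "V")]] +
        BN_MOMENTUM * bn$batchVarUnbiased
      caches[[bi]] <- bn$cache
    } else {
      A <- bnFwdEval(Zi, params[[paste0(bi, "G")]],
                     params[[paste0(bi, "B")]],
                     running[[paste0(bi, "M")]],
                     running[[paste0(bi, "V")]])
    }
    caches[[paste0("c", i, "out")]] <- reluFwd(A)
  }
  # self-attention per particle (residual)
  W <- params[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")]
  Att <- matrix(0, B * Ns, C)
  caches$attn <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * Ns + 1):(b * Ns)
    af <- attnFwd(caches$c2out[rows, , drop = FALSE], W, cfg$nHeads)
    Att[rows, ] <- af$Y
    caches$attn[[b]] <- af$cache
  }
  caches$Att <- Att
  Xhat <- tanhFwd(linFwd(Att, params$outW, params$outb))
  list(Xhat = Xhat, caches = caches, newRun = newRun, B = B, Ns = Ns,
       G = G)
}

decBwd <- function(cfg, params, Z, fw, dXhat) {
  g <- list()
  ca <- fw$caches
  B <- fw$B; Ns <- fw$Ns
  dPre <- tanhBwd(dXhat, fw$Xhat)
  lb <- linBwd(dPre, ca$Att, params$outW)
  g$outW <- lb$dW; g$outb <- lb$db
  dAtt <- lb$dX
  W <- params[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")]
  dC2 <- matrix(0, B * Ns, ncol(dAtt))
  for (nm in names(W)) g[[nm]] <- 0
  for (b in seq_len(B)) {
    rows <- ((b - 1) * Ns + 1):(b * Ns)
    ab <- attnBwd(dAtt[rows, , drop = FALSE], ca$attn[[b]], W)
    dC2[rows, ] <- ab$dX
    for (nm in names(W)) g[[nm]] <- g[[nm]] + ab[[paste0("d", nm)]]
  }
  for (i in 2:1) {
    bi <- paste0("cbn", i); li <- paste0("conv", i)
    dA <- reluBwd(if (i == 2) dC2 else dH0grad,
                  ca[[paste0("c", i, "out")]])
    bb <- bnBwd(dA, ca[[bi]])
    g[[paste0(bi, "G")]] <- bb$dgamma
    g[[paste0(bi, "B")]] <- bb$dbeta
    Xin <- if (i == 1) ca$H0 else ca$c1out
    lb <- linBwd(bb$dX, Xin, params[[paste0(li, "W")]])
    g[[paste0(li, "W")]] <- lb$dW
    g[[paste0(li, "b")]] <- lb$db
    dH0grad <- lb$dX
  }
  dH0 <- dH0grad
  C <- ncol(fw$G)
  dG <- rowsum(dH0[, seq_len(C), drop = FALSE], ca$gidx,
               reorder = TRUE)
  g$emb <- rowsum(dH0[, (C + 1):ncol(dH0), drop = FALSE], ca$eidx,
                  reorder = TRUE)
  g$skipW <- crossprod(Z, dG)
  dZ <- tcrossprod(dG, params$skipW)
  dH <- dG
  for (i in 3:1) {
    bi <- paste0("dbn", i); li <- paste0("dec", i)
    dA <- tanhBwd(dH, ca[[paste0("f", i, "out")]])
    bb <- bnBwd(dA, ca[[bi]])
    g[[paste0(bi, "G")]] <- bb$dgamma
    g[[paste0(bi, "B")]] <- bb$dbeta
    lb <- linBwd(bb$dX, ca[[paste0("f", i, "in")]],
                 params[[paste0(li, "W")]])
    g[[paste0(li, "W")]] <- lb$dW
    g[[paste0(li, "b")]] <- lb$db
    dH <- lb$dX
  }
  dZ <- dZ + dH
  list(grads = g, dZ = dZ)
}

# ---- public operations ---------------------------------------------------

#' Encode one particle into its latent Gaussian
#'
#' Evaluation-mode encoder pass (batch-norm uses running statistics), so
#' the result is deterministic and uses all localizations of the
#' particle. Mean pooling over per-point features makes the output
#' invariant to the ordering of the localizations.
#'
#' @param model a [PCVAE-class].
#' @param X N x p matrix of normalized coordinates in [-1, 1].
#' @return list with \code{mu}, \code{sigma}, \code{logvar} (length-d
#'   numeric vectors).
#' @export
encodeParticle <- function(model, X) {
  stopifnot(is(model, "PCVAE"), is.matrix(X))
  cfg <- model@config
  if (ncol(X) != cfg$p)
    stop("shape error: particle has p = ", ncol(X),
         " but model expects p = ", cfg$p)
  fw <- encFwd(cfg, model@env$params, model@env$running, X,
               rep(1L, nrow(X)), 1L, training = FALSE)
  list(mu = drop(fw$mu), sigma = exp(0.5 * drop(fw$lv)),
       logvar = drop(fw$lv))
}

#' Reparameterized Gaussian sampling
#'
#' \code{z = mu + sigma * eps} with \code{eps ~ N(0, I)}: expresses a
#' latent draw as a deterministic, differentiable function of
#' \code{(mu, sigma)} so gradients flow to the encoder.
#'
#' @param mu,sigma numeric vectors (or matrices) of equal shape;
#'   \code{sigma > 0}.
#' @param eps standard-normal draw of the same shape; drawn internally
#'   when \code{NULL}.
#' @return \code{mu + sigma * eps}.
#' @examples
#' reparameterize(c(1, 2), c(1, 1), c(0.5, -0.5))  # 1.5 1.5
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (is.null(eps)) eps <- stats::rnorm(length(mu))
  if (length(eps) != length(mu)) stop("shape mismatch between mu and eps")
  mu + sigma * eps
}

#' Decode a latent vector into a reconstructed point cloud
#'
#' Evaluation-mode decoder pass; deterministic for fixed weights. The
#' reconstruction always has \code{nOutputPoints} rows regardless of the
#' input particle size, with all coordinates strictly inside (-1, 1)
#' (Tanh output).
#'
#' @param model a [PCVAE-class].
#' @param z numeric vector of length d, or an n x d matrix of latent
#'   vectors.
#' @return \code{nOutputPoints} x p matrix (or a list of matrices for
#'   matrix input).
#' @export
decodeLatent <- function(model, z) {
  stopifnot(is(model, "PCVAE"))
  cfg <- model@config
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, 1) else as.matrix(z)
  if (ncol(Z) != cfg$d)
    stop("shape error: z has length ", ncol(Z), " but d = ", cfg$d)
  fw <- decFwd(cfg, model@env$params, model@env$running, Z,
               training = FALSE)
  if (single) return(fw$Xhat)
  Ns <- cfg$nOutputPoints
  lapply(seq_len(nrow(Z)), function(b)
    fw$Xhat[((b - 1) * Ns + 1):(b * Ns), , drop = FALSE])
}

#' Full auto-encoding pass for one particle
#'
#' encode -> reparameterize (one standard-normal draw) -> decode, in
#' evaluation mode.
#'
#' @param model a [PCVAE-class].
#' @param X N x p normalized coordinate matrix.
#' @param eps optional fixed standard-normal vector (length d).
#' @param seed optional seed for the \code{eps} draw.
#' @return list with \code{reconstruction} (nOutputPoints x p),
#'   \code{mu}, \code{sigma}, \code{z}.
#' @export
pcvaeForward <- function(model, X, eps = NULL, seed = NULL) {
  enc <- encodeParticle(model, X)
  if (is.null(eps)) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    eps <- stats::rnorm(length(enc$mu))
  }
  z <- reparameterize(enc$mu, enc$sigma, eps)
  list(reconstruction = decodeLatent(model, z), mu = enc$mu,
       sigma = enc$sigma, z = z)
}

#' Save / load a PC-VAE checkpoint
#'
#' The checkpoint is a single RDS archive holding the configuration echo,
#' all parameter tensors and batch-norm running statistics. The loader
#' validates the configuration before restoring.
#'
#' @param model a [PCVAE-class].
#' @param path file path.
#' @return \code{saveCheckpoint}: invisibly \code{path};
#'   \code{loadCheckpoint}: the restored [PCVAE-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "PCVAE"))
  saveRDS(list(format = "pcvae-checkpoint-1", config = model@config,
               params = model@env$params, running = model@env$running),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pcvae-checkpoint-1"))
    stop("not a pcvae checkpoint: ", path)
  cfg <- ck$config
  if (!inherits(cfg, "ModelConfig"))
    stop("checkpoint has an invalid model configuration")
  m <- pcvae(cfg, seed = 0L)
  expect <- names(m@env$params)
  if (!setequal(expect, names(ck$params)))
    stop("checkpoint parameters do not match the configuration")
  m@env$params <- ck$params[expect]
  m@env$running <- ck$running
  m
}
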