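#' Default pipeline configuration
#'
#' Nested defaults for every stage; a partial user configuration (e.g. a
#' YAML file) is merged on top, so every documented default is present
#' after loading.
#'
#' @return Nested list with sections \code{seed}, \code{data},
#'   \code{simulate}, \code{model}, \code{train}, \code{loss},
#'   \code{analysis}.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    data = list(path = NULL),             # read instead of simulate
    simulate = list(preset = "npc2d", nParticles = 400L),
    model = list(d = 8L, nOutputPoints = 128L, nHeads = 4L),
    train = list(batchSize = 8L, epochs = 4L, learningRate = 1e-4,
                 weightDecay = 1e-5),
    loss = list(betaMax = 1e-3, warmupSteps = 5000L),
    analysis = list(nBins = 20L, registration = "rot_z",
                    estimator = "npc2d",
                    ratios = c(1, 0.5))
  )
}

#' Load a run configuration from YAML, merged over the defaults
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return The merged configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Run the simulate - train - analyze - estimate pipeline
#'
#' Executes the requested stages in order, writing every stage output
#' plus a manifest (configuration echo, seed, package version, per-stage
#' wall time) into one run directory. Stage randomness derives from one
#' root seed with fixed per-stage offsets, so stages are independently
#' reproducible.
#'
#' @param config a configuration list as from [loadRunConfig()].
#' @param outDir run directory (created; default: a timestamped
#'   directory under \code{tempdir()}).
#' @param stages character subset of
#'   \code{c("simulate", "train", "analyze", "estimate", "robustness")}.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the run directory, the trained model,
#'   latents, correlation report, and per-stage outputs.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        stages = c("simulate", "train", "analyze",
                                   "estimate"),
                        verbose = TRUE) {
  if (is.null(outDir))
    outDir <- file.path(tempdir(),
                        format(Sys.time(), "pcvae-run-%Y%m%d-%H%M%S"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(config = config,
                   package_version =
                     as.character(utils::packageVersion("pcvae")),
                   stages = stages, timing_s = list())
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  res <- list(dir = outDir)
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  truth <- NULL
  if ("simulate" %in% stages) {
    t0 <- tic(); say("stage simulate")
    sim <- tryCatch(
      smlmPreset(config$simulate$preset,
                 nParticles = config$simulate$nParticles,
                 seed = seed + 11L),
      error = function(e) fail("simulate", e))
    ds <- sim$dataset; truth <- sim$truth
    writeLocalizations(ds, file.path(outDir, "dataset.csv"))
    utils::write.csv(truth, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    manifest$timing_s$simulate <- tic() - t0
  } else {
    if (is.null(config$data$path))
      stop("no simulate stage and no data$path configured")
    ds <- readLocalizations(config$data$path)
    tp <- file.path(dirname(config$data$path), "ground_truth.csv")
    if (file.exists(tp)) truth <- utils::read.csv(tp)
  }
  res$dataset <- ds; res$truth <- truth

  norm <- normalizeParticles(ds)
  modelCfg <- do.call(pcvaeConfig,
                      c(list(p = spatialDim(ds)), config$model))
  lossCfg <- do.call(lossConfig, config$loss)
  trainCfg <- do.call(trainConfig,
                      c(config$train,
                        list(seed = seed + 23L, loss = lossCfg)))

  if ("train" %in% stages) {
    t0 <- tic(); say("stage train")
    fit <- tryCatch(trainPCVAE(norm, modelCfg, trainCfg),
                    error = function(e) fail("train", e))
    res$model <- fit$model
    utils::write.csv(fit$history, file.path(outDir, "history.csv"),
                     row.names = FALSE)
    saveCheckpoint(fit$model, file.path(outDir, "checkpoint.rds"))
    manifest$timing_s$train <- tic() - t0
  }

  if (any(c("analyze", "estimate", "robustness") %in% stages)) {
    est <- tryCatch(
      estimateParameters(ds, config$analysis$estimator),
      error = function(e) fail("estimate", e))
    utils::write.csv(est, file.path(outDir, "estimates.csv"),
                     row.names = FALSE)
    res$estimates <- est
  }

  if ("analyze" %in% stages) {
    t0 <- tic(); say("stage analyze")
    lat <- encodeDataset(res$model, norm)
    res$latents <- lat
    utils::write.csv(as.data.frame(lat$mu),
                     file.path(outDir, "latents_mu.csv"),
                     row.names = FALSE)
    ref <- res$estimates$value_nm
    rep <- correlateLatent(lat$mu, ref)
    utils::write.csv(rep, file.path(outDir, "correlations.csv"),
                     row.names = FALSE)
    res$correlations <- rep
    best <- rep$dim[which.max(abs(rep$spearman))]
    assignment <- orderAndBin(lat$mu, dim = best,
                              nBins = config$analysis$nBins)
    binDf <- data.frame(particle_id = particleIds(ds),
                        bin = assignment$binOf)
    utils::write.csv(binDf, file.path(outDir, "bins.csv"),
                     row.names = FALSE)
    res$binAssignment <- assignment
    sps <- superParticles(ds, assignment,
                          mode = config$analysis$registration)
    spDir <- file.path(outDir, "super_particles")
    dir.create(spDir, showWarnings = FALSE)
    cn <- c("x_nm", "y_nm", if (spatialDim(ds) == 3L) "z_nm")
    for (b in seq_along(sps)) {
      m <- as.data.frame(sps[[b]]$points)
      names(m) <- cn
      utils::write.csv(m,
                       file.path(spDir, sprintf("dim%d_bin%02d.csv",
                                                best, b)),
                       row.names = FALSE)
    }
    res$superParticles <- sps
    manifest$timing_s$analyze <- tic() - t0
  }

  if ("robustness" %in% stages) {
    t0 <- tic(); say("stage robustness")
    rc <- tryCatch(
      robustnessCurve(ds, config$analysis$ratios, modelCfg, trainCfg,
                      res$estimates$value_nm),
      error = function(e) fail("robustness", e))
    utils::write.csv(rc, file.path(outDir, "robustness.csv"),
                     row.names = FALSE)
    res$robustness <- rc
    manifest$timing_s$robustness <- tic() - t0
  }

  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(res)
}
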