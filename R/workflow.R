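#' Default run configuration
#'
#' Desk-scale defaults for the full dataset-build / train / restore /
#' evaluate pipeline; every field can be overridden from a YAML file (see
#' [readRunConfig()]). Optimizer settings follow the training recipe used
#' throughout the package: Adam with beta1 = 0.9, beta2 = 0.99, initial
#' learning rate 3e-5 with cosine decay, batch size 2, noise level 50 on
#' the \[0, 255\] range.
#'
#' @param ... named overrides of the defaults.
#' @return a run-config list
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    nPhantoms = 60L, phantomKinds = c("disks", "vessels"),
    gridPx = 64L, spacingMm = 0.2,
    ringElements = 128L, ringRadiusMm = 40, samplingRateMHz = 62.5,
    speedOfSound = 1500,
    mode = "sparse", param = 16,
    filterOrder = 3L, filterBandMHz = c(0.5, 10),
    T = 100L, lambda = 50, thetaKind = "cosine",
    baseChannels = 16L, blocks = c(1L, 1L, 1L, 1L, 1L),
    heads = c(1L, 2L, 4L, 8L, 1L), expansion = 2.66, timeDim = 32L,
    maxSteps = 500L, batchSize = 2L, lr0 = 3e-5,
    beta1 = 0.9, beta2 = 0.99, augment = TRUE, residScale = 0.25,
    fractions = c(0.8, 0.1, 0.1), seed = 1L,
    restoreSteps = NA_integer_)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return a run-config list
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(defaultRunConfig, raw)
}

ringFromConfig <- function(cfg) {
  RingGeometry(radius = cfg$ringRadiusMm, nElements = cfg$ringElements,
               speedOfSound = cfg$speedOfSound,
               samplingRate = cfg$samplingRateMHz,
               imageExtent = cfg$gridPx * cfg$spacingMm)
}

#' Build a paired clean/degraded FBP dataset
#'
#' Simulates full-ring acquisition of every phantom once and reconstructs
#' the full-view reference and the degraded counterpart on the phantom's
#' own grid (see [makeTrainingPair()]).
#'
#' @param images list of \linkS4class{PressureImage} phantoms.
#' @param geom full-ring \linkS4class{RingGeometry}.
#' @param mode,param degradation (see [subsampleViews()]).
#' @param filt a \linkS4class{FilterSpec}.
#' @param progress print a dot every 20 images.
#' @return list of `list(x0 =, mu =)` pairs
#' @export
buildPairedDataset <- function(images, geom, mode, param,
                               filt = FilterSpec(), progress = FALSE) {
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    grid <- ReconGrid(dim(pixels(img))[1],
                      dim(pixels(img))[1] * spacing(img))
    if (progress && i %% 20L == 0L) cat(".")
    makeTrainingPair(img, geom, mode, param, grid, filt)
  })
}

#' Run the full restoration study end to end
#'
#' Generates phantoms, builds degraded/clean FBP pairs, splits them
#' 80/10/10, trains the noise network with the package's training recipe,
#' restores every held-out degraded image along the deterministic exact
#' reverse path (see [reverseSample()], `method = "posterior"`), and
#' evaluates restored-vs-reference and degraded-vs-reference image quality.
#' Training uses dihedral data augmentation and a damped residual-branch
#' initialization by default (both selected on held-out validation images;
#' see the methods vignette). Every stage is driven by the master seed.
#'
#' @param cfg a run config from [defaultRunConfig()] or [readRunConfig()].
#' @param outDir optional directory: writes the frozen config, the loss
#'   log, the checkpoint and the evaluation report there.
#' @param verbose print stage progress.
#' @return list with `report` (restored and degraded [evaluatePairs()]
#'   results), `net`, `log`, `split` sizes, and the config
#' @export
runRestorationStudy <- function(cfg = defaultRunConfig(), outDir = NULL,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating ", cfg$nPhantoms, " phantoms")
  phantoms <- makePhantomDataset(cfg$nPhantoms, cfg$phantomKinds,
                                 grid = cfg$gridPx, spacing = cfg$spacingMm,
                                 seed = cfg$seed)
  geom <- ringFromConfig(cfg)
  filt <- FilterSpec(cfg$filterOrder, cfg$filterBandMHz)
  say("simulating and reconstructing pairs")
  pairs <- buildPairedDataset(phantoms, geom, cfg$mode, cfg$param, filt)
  split <- splitDataset(pairs, cfg$fractions, seed = childSeed(cfg$seed, 1))
  sched <- buildSchedule(cfg$T, cfg$lambda, cfg$thetaKind)
  netCfg <- networkConfig(cfg$baseChannels, cfg$blocks, cfg$heads,
                          cfg$expansion, cfg$timeDim)
  net <- initNoiseNetwork(netCfg, seed = childSeed(cfg$seed, 2),
                          residScale = cfg$residScale)
  say("training for ", cfg$maxSteps, " steps")
  tr <- trainNoiseNetwork(net, split$train, sched, steps = cfg$maxSteps,
                          batchSize = cfg$batchSize, lr0 = cfg$lr0,
                          beta1 = cfg$beta1, beta2 = cfg$beta2,
                          seed = childSeed(cfg$seed, 3),
                          augment = cfg$augment)
  say("restoring ", length(split$test), " test images")
  steps <- if (is.na(cfg$restoreSteps)) nStates(sched) else cfg$restoreSteps
  restored <- withSeed(childSeed(cfg$seed, 4), lapply(split$test, function(pr)
    reverseSample(pr$mu, tr$net, sched, steps = steps,
                  method = "posterior", stochastic = FALSE)))
  refs <- lapply(split$test, function(pr) pixels(pr$x0))
  degraded <- lapply(split$test, function(pr) pixels(pr$mu))
  report <- list(restored = evaluatePairs(refs, restored),
                 degraded = evaluatePairs(refs, degraded))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
    utils::write.csv(tr$log, file.path(outDir, "loss_log.csv"),
                     row.names = FALSE)
    saveCheckpoint(tr$net, file.path(outDir, "checkpoint.rds"),
                   meta = list(seed = cfg$seed, T = cfg$T,
                               lambda = cfg$lambda))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(report = report, net = tr$net, log = tr$log,
       split = vapply(split, length, integer(1)), config = cfg)
}
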