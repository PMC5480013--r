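#' Save / load a trained model
#'
#' Checkpoints are a directory holding a JSON echo of the architecture
#' configuration plus a parameter archive.
#'
#' @param model an [EDDModel-class] or [MuscleModel-class].
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or the model (load), invisibly/visibly.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is(model, "EDDModel")) model@config else model@config
  slots <- slotNames(class(cfg))
  echo <- stats::setNames(lapply(slots, function(s) slot(cfg, s)), slots)
  jsonlite::write_json(list(class = class(model)[1], config = echo),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  saveRDS(model, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  readRDS(file.path(dir, "params.rds"))
}

.pipelineKeys <- c("outDir", "nTrainSubjects", "nTestSubjects", "phantom",
                   "network", "muscle", "eddTrain", "muscleTrain",
                   "valFraction", "seed", "stages", "useMuscle")

#' Pipeline configuration
#'
#' Bundles all stage configurations with a global seed and stage
#' toggles. Unknown arguments are rejected so that config typos cannot
#' silently corrupt a run.
#'
#' @param outDir output directory.
#' @param nTrainSubjects,nTestSubjects phantom cohort sizes.
#' @param phantom a [PhantomConfig-class].
#' @param network a [NetworkConfig-class].
#' @param muscle a [MuscleConfig-class].
#' @param eddTrain,muscleTrain [TrainConfig-class] objects.
#' @param valFraction subject fraction held out for validation.
#' @param seed global seed; stage seeds are derived from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "train-edd", "train-muscle", "segment", "evaluate")`.
#'   Disabled stages must find their outputs on disk.
#' @param useMuscle if FALSE, segmentation stops after stage 1 (the
#'   ensemble encoder-decoder alone).
#' @return a named list with class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir = "dwiseg-run",
                           nTrainSubjects = 14L, nTestSubjects = 6L,
                           phantom = phantomConfig(),
                           network = networkConfig(),
                           muscle = muscleConfig(),
                           eddTrain = trainConfig(),
                           muscleTrain = trainConfig(maxEpochs = 30L),
                           valFraction = 0.3, seed = 1L,
                           stages = c("simulate", "train-edd", "train-muscle",
                                      "segment", "evaluate"),
                           useMuscle = TRUE) {
  cfg <- list(outDir = outDir, nTrainSubjects = as.integer(nTrainSubjects),
              nTestSubjects = as.integer(nTestSubjects), phantom = phantom,
              network = network, muscle = muscle, eddTrain = eddTrain,
              muscleTrain = muscleTrain, valFraction = valFraction,
              seed = as.integer(seed), stages = stages,
              useMuscle = isTRUE(useMuscle))
  bad <- setdiff(stages, c("simulate", "train-edd", "train-muscle",
                           "segment", "evaluate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipelineConfig()] arguments; the nested
#' `phantom`, `network`, `muscle`, `eddTrain` and `muscleTrain` maps are
#' passed to the corresponding constructors. Unknown keys anywhere are
#' rejected.
#'
#' @param path YAML file path.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  checkKeys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  checkKeys(y, .pipelineKeys, "pipeline config")
  sub <- function(key, fn) {
    if (is.null(y[[key]])) return(NULL)
    checkKeys(y[[key]], names(formals(fn)), key)
    do.call(fn, y[[key]])
  }
  args <- y
  for (key in c("phantom", "network", "muscle")) {
    v <- sub(key, switch(key, phantom = phantomConfig,
                         network = networkConfig, muscle = muscleConfig))
    if (!is.null(v)) args[[key]] <- v
  }
  for (key in c("eddTrain", "muscleTrain")) {
    v <- sub(key, trainConfig)
    if (!is.null(v)) args[[key]] <- v
  }
  do.call(pipelineConfig, args)
}

.digestFiles <- function(files) {
  files <- sort(files[file.exists(files)])
  md <- tools::md5sum(files)
  stats::setNames(as.vector(md), basename(files))
}

# Build the candidate training data for the second stage by running the
# stage-1 model over a set of subjects.
.muscleTrainingData <- function(edd, subjects, mcfg) {
  stacksList <- list(); labels <- integer(0)
  os <- mcfg@outputSide
  for (s in subjects) {
    vol <- normalizeIntensity(resampleInPlane(s@volume))
    gt <- resampleInPlane(s@lesionMask)
    p <- predictVolume(edd, vol)
    mask <- binarize(p, mcfg@threshold, inPlaneSpacing(vol),
                     sliceSpacing(vol), subjectID(vol))
    cands <- findCandidates(mask, p, mcfg@smallObjectLimit,
                            mcfg@connectivity)
    if (length(cands$small) == 0L) next
    labs <- labelCandidates(cands$small, gt)
    for (i in seq_along(cands$small)) {
      stacksList[[length(stacksList) + 1L]] <-
        extractStack(vol@voxels[, , cands$small[[i]]@slice], p,
                     cands$small[[i]], mcfg)
    }
    labels <- c(labels, labs)
  }
  if (length(stacksList) == 0L)
    return(list(stacks = array(0, c(os, os, 4L, 0L)), labels = integer(0)))
  stacks <- array(0, c(os, os, 4L, length(stacksList)))
  for (i in seq_along(stacksList)) stacks[, , , i] <- stacksList[[i]]
  list(stacks = stacks, labels = labels)
}

#' Run the full segmentation pipeline
#'
#' Executes the enabled stages in order: phantom simulation, stage-1
#' network training, candidate-classifier training, whole-volume
#' segmentation of the test subjects, and evaluation. Every stage writes
#' its outputs under `cfg$outDir` and a run manifest (config echo,
#' per-stage output digests, durations, package version) is written at
#' the end. All randomness is derived from `cfg$seed`, so a rerun with
#' an identical configuration reproduces all output digests.
#'
#' @param cfg a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  out <- cfg$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = .echoConfig(cfg), stages = list(),
                   version = as.character(utils::packageVersion("dwiseg")))
  note <- function(stage, t0, files) {
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      digests = as.list(.digestFiles(files)))
  }
  run <- function(stage) stage %in% cfg$stages

  trainDir <- file.path(out, "train"); testDir <- file.path(out, "test")
  if (run("simulate")) {
    t0 <- as.numeric(Sys.time())
    trainCohort <- generateCohort(cfg$phantom, cfg$nTrainSubjects)
    testCohort <- generateCohort(cfg$phantom, cfg$nTestSubjects,
                                 firstSeed = cfg$nTrainSubjects + 1L)
    writeCohort(trainCohort, trainDir)
    writeCohort(testCohort, testDir)
    note("simulate", t0, c(list.files(trainDir, full.names = TRUE),
                           list.files(testDir, full.names = TRUE)))
    if (verbose) message("simulate: done")
  }
  loadCohort <- function(dir) {
    man <- utils::read.csv(file.path(dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    lapply(man$subject_id, function(sid) {
      list(volume = readVolume(file.path(dir, paste0(sid, "_dwi.nii.gz")),
                               "image", sid),
           mask = readVolume(file.path(dir, paste0(sid, "_mask.nii.gz")),
                             "mask", sid))
    })
  }

  eddDir <- file.path(out, "edd-model")
  if (run("train-edd")) {
    t0 <- as.numeric(Sys.time())
    trainPairs <- loadCohort(trainDir)
    sets <- buildTrainingSet(trainPairs, patchSize = cfg$network@patchSize,
                             seed = .deriveSeed(cfg$seed, 11L),
                             valFraction = cfg$valFraction)
    ecfg <- cfg$eddTrain; ecfg@seed <- .deriveSeed(cfg$seed, 13L)
    edd <- trainEDD(sets$train, sets$val, cfg$network, ecfg,
                    verbose = verbose)
    saveModel(edd, eddDir)
    utils::write.csv(edd@log, file.path(eddDir, "log.csv"),
                     row.names = FALSE)
    note("train-edd", t0, file.path(eddDir, c("config.json", "log.csv")))
    if (verbose) message("train-edd: done")
  }

  muscleDir <- file.path(out, "muscle-model")
  if (run("train-muscle") && cfg$useMuscle) {
    t0 <- as.numeric(Sys.time())
    edd <- loadModel(eddDir)
    trainPairs <- loadCohort(trainDir)
    subjects <- lapply(trainPairs, function(pr)
      new("PhantomSubject", volume = pr$volume, lesionMask = pr$mask,
          artefactMask = LesionMask(array(0, dim(pr$mask@voxels)),
                                    inPlaneSpacing(pr$mask),
                                    sliceSpacing(pr$mask)),
          manifestRow = data.frame(subject_id = subjectID(pr$volume),
                                   n_lesions = NA, mean_size = NA,
                                   class = NA, seed = NA)))
    td <- .muscleTrainingData(edd, subjects, cfg$muscle)
    mcfg <- cfg$muscleTrain; mcfg@seed <- .deriveSeed(cfg$seed, 17L)
    muscle <- trainMuscle(td$stacks, td$labels, cfg$muscle, mcfg,
                          verbose = verbose)
    saveModel(muscle, muscleDir)
    utils::write.csv(muscle@log, file.path(muscleDir, "log.csv"),
                     row.names = FALSE)
    note("train-muscle", t0,
         file.path(muscleDir, c("config.json", "log.csv")))
    if (verbose) message("train-muscle: done")
  }

  segDir <- file.path(out, "segmentations")
  if (run("segment")) {
    t0 <- as.numeric(Sys.time())
    dir.create(segDir, showWarnings = FALSE)
    edd <- loadModel(eddDir)
    muscle <- if (cfg$useMuscle) loadModel(muscleDir) else NULL
    testPairs <- loadCohort(testDir)
    candRows <- list()
    for (pr in testPairs) {
      vol <- normalizeIntensity(resampleInPlane(pr$volume))
      p <- predictVolume(edd, vol)
      if (cfg$useMuscle) {
        ref <- refineSegmentation(p, muscle, vol, cfg$muscle)
        mask <- ref$mask
        if (nrow(ref$candidates)) {
          ref$candidates$subject <- subjectID(vol)
          candRows[[length(candRows) + 1L]] <- ref$candidates
        }
      } else {
        mask <- binarize(p, cfg$muscle@threshold, inPlaneSpacing(vol),
                         sliceSpacing(vol), subjectID(vol))
      }
      writeVolume(mask, file.path(segDir,
                                  paste0(subjectID(vol), "_pred.nii.gz")))
    }
    if (length(candRows))
      utils::write.csv(do.call(rbind, candRows),
                       file.path(segDir, "candidates.csv"),
                       row.names = FALSE)
    note("segment", t0, list.files(segDir, full.names = TRUE))
    if (verbose) message("segment: done")
  }

  if (run("evaluate")) {
    t0 <- as.numeric(Sys.time())
    testPairs <- loadCohort(testDir)
    evals <- lapply(testPairs, function(pr) {
      pred <- readVolume(file.path(segDir, paste0(subjectID(pr$volume),
                                                  "_pred.nii.gz")), "mask")
      gt <- resampleInPlane(pr$mask)
      evaluateSubject(pred, gt, subjectID(pr$volume),
                      cfg$muscle@connectivity)
    })
    report <- cohortReport(evals)
    repPath <- file.path(out, "report.csv")
    utils::write.csv(report@subjects, repPath, row.names = FALSE)
    utils::write.csv(report@summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(report@summary), file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("evaluate", t0, c(repPath, file.path(out, c("summary.csv",
                                                     "summary.json"))))
    if (verbose) message("evaluate: done")
  }

  jsonPath <- file.path(out, "manifest.json")
  tmp <- paste0(jsonPath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, jsonPath)
  invisible(manifest)
}

.echoConfig <- function(cfg) {
  echoS4 <- function(x) {
    slots <- slotNames(class(x))
    stats::setNames(lapply(slots, function(s) slot(x, s)), slots)
  }
  list(outDir = cfg$outDir, nTrainSubjects = cfg$nTrainSubjects,
       nTestSubjects = cfg$nTestSubjects, phantom = echoS4(cfg$phantom),
       network = echoS4(cfg$network), muscle = echoS4(cfg$muscle),
       eddTrain = echoS4(cfg$eddTrain), muscleTrain = echoS4(cfg$muscleTrain),
       valFraction = cfg$valFraction, seed = cfg$seed,
       stages = cfg$stages, useMuscle = cfg$useMuscle)
}

# Probability map of one subject under a chosen model variant.
.predictVolumeVariant <- function(edd, vol, variant, branch = 1L) {
  div <- edd@config@poolWindow^(edd@config@convStacks - 1L)
  maps <- lapply(volumeSlices(vol), function(s) {
    H <- nrow(s); W <- ncol(s)
    H2 <- as.integer(ceiling(H / div) * div)
    W2 <- as.integer(ceiling(W / div) * div)
    x <- array(.padReflect(s, H2, W2), c(H2, W2, 1L, 1L))
    pm <- switch(variant,
      branch = .netForward(edd@branches[[branch]], x, FALSE)$out,
      ensemble = ensembleForward(edd, x),
      edd = .eddForward(edd, x, FALSE)$H)
    pm[seq_len(H), seq_len(W), , 1L, drop = FALSE]
  })
  d <- dim(maps[[1]])
  out <- array(0, c(d[1], d[2], 2L, length(maps)))
  for (k in seq_along(maps)) out[, , , k] <- maps[[k]][, , , 1]
  new("ProbabilityMap", probs = out)
}

#' Ablation comparison of the cascade's stages
#'
#' Evaluates, on the same test subjects, each single branch, the naive
#' ensemble, the refined stage-1 network, and (optionally) the full
#' cascade with candidate evaluation. One metric row per variant.
#'
#' @param edd a trained [EDDModel-class].
#' @param muscle a trained [MuscleModel-class] or NULL.
#' @param testPairs list of `list(volume = , mask = )` test subjects
#'   (raw; preprocessing is applied internally).
#' @param mcfg a [MuscleConfig-class].
#' @return data.frame with one row per variant and the cohort metric
#'   columns.
#' @export
ablationReport <- function(edd, muscle, testPairs, mcfg = muscleConfig()) {
  variants <- c(paste0("branch", seq_along(edd@branches)), "ensemble", "edd")
  if (!is.null(muscle)) variants <- c(variants, "edd+muscle")
  rows <- list()
  pre <- lapply(testPairs, function(pr)
    list(vol = normalizeIntensity(resampleInPlane(pr$volume)),
         gt = resampleInPlane(pr$mask)))
  for (v in variants) {
    evals <- lapply(pre, function(pr) {
      if (v == "edd+muscle") {
        p <- .predictVolumeVariant(edd, pr$vol, "edd")
        mask <- refineSegmentation(p, muscle, pr$vol, mcfg)$mask
      } else {
        variant <- if (startsWith(v, "branch")) "branch" else v
        br <- if (variant == "branch") as.integer(sub("branch", "", v)) else 1L
        p <- .predictVolumeVariant(edd, pr$vol, variant, br)
        mask <- binarize(p, mcfg@threshold, inPlaneSpacing(pr$vol),
                         sliceSpacing(pr$vol), subjectID(pr$vol))
      }
      evaluateSubject(mask, pr$gt, subjectID(pr$vol), mcfg@connectivity)
    })
    s <- cohortReport(evals)@summary
    s <- cbind(variant = v, s)
    rows[[length(rows) + 1L]] <- s
  }
  do.call(rbind, rows)
}
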