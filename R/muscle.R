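#' Configuration of the candidate evaluation stage
#'
#' @param threshold binarisation threshold (default 0.5, the
#'   argmax-equivalent for two classes).
#' @param smallObjectLimit components of at most this many pixels are
#'   evaluated by the classifier; larger ones are kept unconditionally
#'   (default 60 px, the size below which essentially all false
#'   positives fall).
#' @param connectivity 4 or 8 (default 8; components are 2-d slice-wise).
#' @param outputSide side of the resized multi-scale patches (default 16).
#' @param convChannels,fcWidths network widths (defaults 32,32,64,64 and
#'   128,64,2).
#' @return a [MuscleConfig-class].
#' @export
muscleConfig <- function(threshold = 0.5, smallObjectLimit = 60L,
                         connectivity = 8L, outputSide = 16L,
                         convChannels = c(32L, 32L, 64L, 64L),
                         fcWidths = c(128L, 64L, 2L)) {
  cfg <- new("MuscleConfig", threshold = threshold,
             smallObjectLimit = as.integer(smallObjectLimit),
             connectivity = as.integer(connectivity),
             outputSide = as.integer(outputSide),
             convChannels = as.integer(convChannels),
             fcWidths = as.integer(fcWidths))
  validObject(cfg)
  cfg
}

#' Binarise a probability map
#'
#' @param p a [ProbabilityMap-class].
#' @param threshold pixels with lesion-class probability `>= threshold`
#'   become 1; must lie strictly inside (0, 1).
#' @param spacing,sliceSpacing,subjectID metadata for the returned mask.
#' @return a [LesionMask-class].
#' @export
binarize <- function(p, threshold = 0.5, spacing = c(1.6, 1.6),
                     sliceSpacing = 5, subjectID = "subject") {
  stopifnot(is(p, "ProbabilityMap"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  v <- (p@probs[, , 2, ] >= threshold) * 1
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  LesionMask(v, spacing, sliceSpacing, subjectID)
}

# All connected components of a binary volume, labelled slice-wise.
.allComponents <- function(voxels, connectivity = 8L) {
  out <- list()
  id <- 0L
  for (k in seq_len(dim(voxels)[3])) {
    lab <- label_components(matrix(as.integer(voxels[, , k]), nrow(voxels)),
                            connectivity)
    ncomp <- max(lab)
    if (ncomp == 0L) next
    for (ci in seq_len(ncomp)) {
      px2 <- which(lab == ci, arr.ind = TRUE)
      id <- id + 1L
      out[[id]] <- list(id = id, slice = k, px = px2)
    }
  }
  out
}

#' Candidate lesions from a binarised map
#'
#' Connected components are labelled slice-wise (8-connectivity by
#' default). Components whose size is at most `limit` pixels are "small"
#' candidates, to be evaluated by the classifier; larger components
#' bypass evaluation and are always kept.
#'
#' @param mask a [LesionMask-class] (the binarised probability map).
#' @param p the matching [ProbabilityMap-class].
#' @param limit small-object size limit in pixels (default 60).
#' @param connectivity 4 or 8.
#' @return list with `small` and `large`: lists of
#'   [CandidateLesion-class].
#' @export
findCandidates <- function(mask, p, limit = 60L, connectivity = 8L) {
  stopifnot(is(mask, "LesionMask"), is(p, "ProbabilityMap"))
  if (!identical(dim(mask@voxels), dim(p@probs)[c(1, 2, 4)]))
    stop("mask and probability map are not congruent")
  comps <- .allComponents(mask@voxels, connectivity)
  small <- list(); large <- list()
  for (co in comps) {
    px2 <- co$px
    probsHere <- p@probs[, , 2, co$slice][px2]
    cand <- new("CandidateLesion", id = co$id,
                pixels = cbind(slice = rep(co$slice, nrow(px2)),
                               row = px2[, 1], col = px2[, 2]),
                size = nrow(px2),
                centroid = c(mean(px2[, 1]), mean(px2[, 2])),
                bbox = as.integer(c(min(px2[, 1]), min(px2[, 2]),
                                    max(px2[, 1]), max(px2[, 2]))),
                slice = co$slice, meanProb = mean(probsHere))
    if (cand@size <= limit) small[[length(small) + 1L]] <- cand
    else large[[length(large) + 1L]] <- cand
  }
  list(small = small, large = large)
}

# Extract a square window of side L centred on (r, c), zero-padded.
.window <- function(m, r, c, L) {
  out <- matrix(0, L, L)
  r0 <- round(r) - floor(L / 2); c0 <- round(c) - floor(L / 2)
  rs <- max(1L, r0):min(nrow(m), r0 + L - 1L)
  cs <- max(1L, c0):min(ncol(m), c0 + L - 1L)
  if (length(rs) > 0L && length(cs) > 0L && rs[1] <= rs[length(rs)])
    out[rs - r0 + 1L, cs - c0 + 1L] <- m[rs, cs]
  out
}

#' Multi-scale patch stack for one candidate
#'
#' The base scale is `s = max(longest bounding-box side, 8)` pixels.
#' Square windows of sides s, 2s and 4s are extracted from the image
#' around the candidate centroid (zero-padded outside the slice), plus
#' the s-window of the lesion-probability channel; all four are
#' bilinearly resized to `outputSide x outputSide` and concatenated in
#' channel order (img_s, img_2s, img_4s, prob_s).
#'
#' @param slice 2-d image matrix of the candidate's slice.
#' @param p the [ProbabilityMap-class] of the subject.
#' @param cand a [CandidateLesion-class].
#' @param cfg a [MuscleConfig-class].
#' @return numeric array (outputSide, outputSide, 4).
#' @export
extractStack <- function(slice, p, cand, cfg = muscleConfig()) {
  stopifnot(is(cand, "CandidateLesion"))
  if (cand@size < 1L) stop("degenerate candidate with no pixels")
  s <- max(cand@bbox[3] - cand@bbox[1] + 1L, cand@bbox[4] - cand@bbox[2] + 1L,
           8L)
  pm <- p@probs[, , 2, cand@slice]
  os <- cfg@outputSide
  rs <- function(w) EBImage::resize(w, w = os, h = os, filter = "bilinear")
  out <- array(0, c(os, os, 4L))
  out[, , 1] <- rs(.window(slice, cand@centroid[1], cand@centroid[2], s))
  out[, , 2] <- rs(.window(slice, cand@centroid[1], cand@centroid[2], 2L * s))
  out[, , 3] <- rs(.window(slice, cand@centroid[1], cand@centroid[2], 4L * s))
  out[, , 4] <- rs(.window(pm, cand@centroid[1], cand@centroid[2], s))
  out
}

#' Build the candidate classification network
#'
#' A mini VGG-style classifier: four 3x3 convolutions (batch norm + ReLU
#' after each), one 2x2 max pooling after the first two, and three fully
#' connected layers ending in a 2-class softmax.
#'
#' @param cfg a [MuscleConfig-class].
#' @param seed integer seed for Xavier initialisation.
#' @return a [MuscleModel-class] with `trained = FALSE`.
#' @export
buildMuscleNet <- function(cfg = muscleConfig(), seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.deriveSeed(seed, 200L))
  cc <- cfg@convChannels; fw <- cfg@fcWidths
  half <- cfg@outputSide %/% 2L
  layers <- list(
    .layerConv(4L, cc[1], 3L), .layerBN(cc[1]), .layerReLU(),
    .layerConv(cc[1], cc[2], 3L), .layerBN(cc[2]), .layerReLU(),
    .layerPool(2L, "p1"),
    .layerConv(cc[2], cc[3], 3L), .layerBN(cc[3]), .layerReLU(),
    .layerConv(cc[3], cc[4], 3L), .layerBN(cc[4]), .layerReLU(),
    .layerFlatten(),
    .layerFC(half * half * cc[4], fw[1]), .layerReLUv(),
    .layerFC(fw[1], fw[2]), .layerReLUv(),
    .layerFC(fw[2], fw[3]), .layerSoftmaxv())
  new("MuscleModel", config = cfg, params = layers, log = data.frame(),
      trained = FALSE)
}

#' Label candidates against a ground-truth mask
#'
#' A candidate is a true lesion (label 1) if and only if its pixel set
#' overlaps the ground truth in at least one pixel.
#'
#' @param candidates list of [CandidateLesion-class].
#' @param gt a [LesionMask-class] in the same coordinate frame.
#' @return integer vector of 0/1 labels.
#' @export
labelCandidates <- function(candidates, gt) {
  stopifnot(is(gt, "LesionMask"))
  vapply(candidates, function(cand) {
    px <- cand@pixels
    as.integer(any(gt@voxels[cbind(px[, 2], px[, 3], px[, 1])] > 0))
  }, integer(1))
}

# Forward a stack batch (os, os, 4, N) through the classifier.
.muscleForward <- function(model, x, training = FALSE) {
  .netForward(model@params, x, training)
}

#' Train the candidate classification network
#'
#' SGD with momentum on the instance-level cross-entropy. Minibatches are
#' balanced by oversampling the minority class. A stratified validation
#' split is held out and the parameters with the best validation accuracy
#' are returned.
#'
#' @param stacks array (outputSide, outputSide, 4, N) of candidate
#'   stacks.
#' @param labels integer 0/1 labels (both classes must be present).
#' @param cfg a [MuscleConfig-class].
#' @param trainCfg a [TrainConfig-class] (defaults: 30 epochs).
#' @param valFraction fraction held out for model selection.
#' @param verbose print per-epoch progress.
#' @return a trained [MuscleModel-class].
#' @export
trainMuscle <- function(stacks, labels, cfg = muscleConfig(),
                        trainCfg = trainConfig(maxEpochs = 30L),
                        valFraction = 0.2, verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both candidate classes must be present in the training set")
  if (dim(stacks)[4] != length(labels))
    stop("stacks and labels disagree in length")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  model <- buildMuscleNet(cfg, seed = trainCfg@seed)
  vel <- .sgdInitVelocity(model@params)
  set.seed(.deriveSeed(trainCfg@seed, 300L))
  n <- length(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  nvalP <- max(1L, floor(length(pos) * valFraction))
  nvalN <- max(1L, floor(length(neg) * valFraction))
  valIdx <- c(sample(pos, nvalP), sample(neg, nvalN))
  trIdx <- setdiff(seq_len(n), valIdx)
  trPos <- intersect(trIdx, pos); trNeg <- intersect(trIdx, neg)
  if (length(trPos) == 0L || length(trNeg) == 0L)
    stop("both candidate classes must survive the validation split")
  bs <- trainCfg@batchSize
  bestAcc <- -Inf; best <- model@params
  logRows <- list()
  evalAcc <- function(idx) {
    x <- stacks[, , , idx, drop = FALSE]
    out <- .muscleForward(model, x, FALSE)$out
    mean((out[, 2] >= 0.5) == (labels[idx] == 1L))
  }
  for (epoch in seq_len(trainCfg@maxEpochs)) {
    # balance by oversampling the minority class
    m <- max(length(trPos), length(trNeg))
    epPos <- if (length(trPos) < m) sample(trPos, m, replace = TRUE) else sample(trPos)
    epNeg <- if (length(trNeg) < m) sample(trNeg, m, replace = TRUE) else sample(trNeg)
    ord <- sample(c(epPos, epNeg))
    epochLoss <- 0; nb <- 0L
    for (at in seq(1L, length(ord), by = bs)) {
      idx <- ord[at:min(length(ord), at + bs - 1L)]
      x <- stacks[, , , idx, drop = FALSE]
      y <- labels[idx]
      fw <- .muscleForward(model, x, TRUE)
      model@params <- fw$layers
      loss <- .ceInstance(fw$out, y)
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
      epochLoss <- epochLoss + loss; nb <- nb + 1L
      g <- .ceInstanceGrad(fw$out, y)
      bk <- .netBackward(model@params, fw$caches, g)
      st <- .sgdStep(model@params, bk$grads, vel, trainCfg@learningRate,
                     trainCfg@momentum, trainCfg@weightDecay)
      model@params <- st$layers; vel <- st$vel
    }
    acc <- evalAcc(valIdx)
    logRows[[epoch]] <- data.frame(epoch = epoch, train_loss = epochLoss / nb,
                                   val_acc = acc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val acc %.4f", epoch,
                      epochLoss / nb, acc))
    if (acc > bestAcc) { bestAcc <- acc; best <- model@params }
  }
  model@params <- best
  model@log <- do.call(rbind, logRows)
  model@trained <- TRUE
  model
}

#' Classify candidate stacks
#'
#' @param model a trained [MuscleModel-class].
#' @param stacks array (outputSide, outputSide, 4, N).
#' @return numeric vector of instance-level lesion probabilities.
#' @export
muscleClassify <- function(model, stacks) {
  stopifnot(is(model, "MuscleModel"))
  if (length(dim(stacks)) == 3L) stacks <- array(stacks, c(dim(stacks), 1L))
  .muscleForward(model, stacks, FALSE)$out[, 2]
}

#' Fuse an instance-level probability into the pixel map
#'
#' Treats the classifier's instance probability `q` as independent
#' evidence and multiplies it into the per-pixel lesion odds of the
#' candidate's pixels: with `qt = clip(q, 1e-6, 1 - 1e-6)`,
#' `p' = p * qt / (p * qt + (1 - p) * (1 - qt))`. `q = 0.5` is neutral
#' (identity), `q -> 0` removes the component, `q -> 1` reinforces it.
#' Pixels outside the candidate are untouched; the background channel is
#' renormalised.
#'
#' @param p a [ProbabilityMap-class].
#' @param cand a [CandidateLesion-class].
#' @param q instance probability in \[0, 1\].
#' @return the fused [ProbabilityMap-class].
#' @export
bayesFuse <- function(p, cand, q) {
  stopifnot(is(p, "ProbabilityMap"), is(cand, "CandidateLesion"))
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a single probability in [0, 1]")
  qt <- min(max(q, 1e-6), 1 - 1e-6)
  px <- cand@pixels
  out <- p@probs
  idx2 <- cbind(px[, 2], px[, 3], rep(2L, nrow(px)), px[, 1])
  pi_ <- out[idx2]
  pf <- pi_ * qt / (pi_ * qt + (1 - pi_) * (1 - qt))
  out[idx2] <- pf
  out[cbind(px[, 2], px[, 3], rep(1L, nrow(px)), px[, 1])] <- 1 - pf
  new("ProbabilityMap", probs = out)
}

#' Remove false positives from a stage-1 segmentation
#'
#' Binarises the probability map, finds connected components, evaluates
#' every small candidate with the classifier ([extractStack()] +
#' [muscleClassify()]), fuses each instance probability into the pixel
#' map ([bayesFuse()]) and re-binarises at the same threshold. Large
#' components bypass evaluation and are always retained; the refined
#' mask never contains pixels absent from the stage-1 binarisation.
#'
#' @param p stage-1 [ProbabilityMap-class] of the subject.
#' @param model a trained [MuscleModel-class].
#' @param vol the preprocessed [DWIVolume-class] (for image windows).
#' @param cfg a [MuscleConfig-class].
#' @return list with `prob` (fused [ProbabilityMap-class]), `mask`
#'   (refined [LesionMask-class]) and `candidates` (a data.frame:
#'   slice, size, centroid, q, kept).
#' @export
refineSegmentation <- function(p, model, vol, cfg = muscleConfig()) {
  stopifnot(is(p, "ProbabilityMap"), is(vol, "DWIVolume"))
  if (!model@trained) stop("the candidate classifier has not been trained")
  mask0 <- binarize(p, cfg@threshold, inPlaneSpacing(vol), sliceSpacing(vol),
                    subjectID(vol))
  cands <- findCandidates(mask0, p, cfg@smallObjectLimit, cfg@connectivity)
  rows <- list()
  for (cand in cands$large)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = cand@slice, size = cand@size, centroid_r = cand@centroid[1],
      centroid_c = cand@centroid[2], q = NA_real_, kept = TRUE)
  if (length(cands$small) > 0L) {
    os <- cfg@outputSide
    stacks <- array(0, c(os, os, 4L, length(cands$small)))
    for (i in seq_along(cands$small))
      stacks[, , , i] <- extractStack(vol@voxels[, , cands$small[[i]]@slice],
                                      p, cands$small[[i]], cfg)
    qs <- muscleClassify(model, stacks)
    for (i in seq_along(cands$small)) {
      p <- bayesFuse(p, cands$small[[i]], qs[i])
      cand <- cands$small[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        slice = cand@slice, size = cand@size, centroid_r = cand@centroid[1],
        centroid_c = cand@centroid[2], q = qs[i], kept = NA)
    }
  }
  mask <- binarize(p, cfg@threshold, inPlaneSpacing(vol), sliceSpacing(vol),
                   subjectID(vol))
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(0), size = integer(0),
               centroid_r = numeric(0), centroid_c = numeric(0),
               q = numeric(0), kept = logical(0))
  if (nrow(candidates) > 0L && anyNA(candidates$kept)) {
    # a small candidate is kept if any of its pixels survived
    smallIdx <- which(is.na(candidates$kept))
    for (j in seq_along(smallIdx)) {
      cand <- cands$small[[j]]
      px <- cand@pixels
      candidates$kept[smallIdx[j]] <-
        any(mask@voxels[cbind(px[, 2], px[, 3], px[, 1])] > 0)
    }
  }
  list(prob = p, mask = mask, candidates = candidates)
}
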