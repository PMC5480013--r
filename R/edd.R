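#' Network configuration for the ensemble encoder-decoder
#'
#' Defaults follow the operating point used for DWI lesion segmentation:
#' an ensemble of `nBranches = 2` branches, each with three stacks of two
#' 3x3 stride-1 convolutions and two mask-recording 2x2 poolings, base
#' width 32 doubling per stack, trained on 64x64 patches, with a
#' three-convolution refinement head.
#'
#' @param nBranches,convStacks,convsPerStack,baseChannels,patchSize,poolWindow,refinementConvs
#'   see [NetworkConfig-class].
#' @return a [NetworkConfig-class]. A warning is issued if the derived
#'   receptive field exceeds the patch size.
#' @export
networkConfig <- function(nBranches = 2L, convStacks = 3L, convsPerStack = 2L,
                          baseChannels = 32L, patchSize = 64L,
                          poolWindow = 2L, refinementConvs = 3L) {
  cfg <- new("NetworkConfig", nBranches = as.integer(nBranches),
             convStacks = as.integer(convStacks),
             convsPerStack = as.integer(convsPerStack),
             baseChannels = as.integer(baseChannels),
             patchSize = as.integer(patchSize),
             poolWindow = as.integer(poolWindow),
             refinementConvs = as.integer(refinementConvs))
  validObject(cfg)
  rf <- receptiveField(cfg)
  if (rf > cfg@patchSize)
    warning(sprintf("receptive field (%d px) exceeds the patch size (%d px)",
                    rf, cfg@patchSize))
  cfg
}

#' Training configuration
#'
#' @param learningRate,momentum,weightDecay,lambda,batchSize,maxEpochs,seed,augment
#'   see [TrainConfig-class]. `lambda` of length 1 is recycled to the
#'   N + 2 loss terms at training time.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.05, momentum = 0.9,
                        weightDecay = 0, lambda = 1, batchSize = 32L,
                        maxEpochs = 40L, seed = 1L, augment = TRUE) {
  cfg <- new("TrainConfig", learningRate = learningRate, momentum = momentum,
             weightDecay = weightDecay, lambda = lambda,
             batchSize = as.integer(batchSize),
             maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
             augment = augment)
  validObject(cfg)
  cfg
}

.as4d <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) array(x, c(dim(x), 1L))
  else x
}

#' Max pooling with recorded activation locations
#'
#' Non-overlapping `window x window` max pooling with stride equal to the
#' window. For every pooled cell the within-window location of the
#' maximum is recorded in a [PoolingMask-class]; ties are broken by the
#' first position in row-major order. The mask later inverts pooling in
#' the decoder.
#'
#' @param f feature map: matrix, (H, W, C) or (H, W, C, N) array.
#' @param window pooling window side (default 2).
#' @return list with `pooled` (array, spatial side divided by `window`)
#'   and `mask` (a [PoolingMask-class]).
#' @export
maxPoolWithMask <- function(f, window = 2L) {
  x <- .as4d(f)
  r <- maxpool_fwd(x, as.integer(window))
  list(pooled = r$out,
       mask = new("PoolingMask", index = r$mask, window = as.integer(window)))
}

#' Unpooling driven by a pooling mask
#'
#' Sparse upsampling: each pooled value is placed at its recorded
#' location within its window; all other positions are zero. The output
#' spatial side is the pooled side times the window.
#'
#' @param pooled pooled feature map (as returned by [maxPoolWithMask()]).
#' @param mask the matching [PoolingMask-class].
#' @return the unpooled array.
#' @export
unpoolWithMask <- function(pooled, mask) {
  stopifnot(is(mask, "PoolingMask"))
  x <- .as4d(pooled)
  if (!identical(dim(x), dim(mask@index)))
    stop("pooled map and mask shapes do not match")
  unpool_fwd(x, mask@index, mask@window)
}

.stackWidth <- function(cfg, s) cfg@baseChannels * 2L^(s - 1L)

#' Build one encoder-decoder branch
#'
#' The encoder is `convStacks` stacks of `convsPerStack` 3x3 stride-1
#' convolutions (each followed by batch normalisation and ReLU) with a
#' mask-recording pooling between consecutive stacks; the decoder mirrors
#' the encoder, consuming the corresponding pooling masks in reverse
#' order, and ends in a 1x1 convolution to 2 classes with a per-pixel
#' softmax. All convolutions pad to preserve spatial size.
#'
#' @param cfg a [NetworkConfig-class].
#' @param inChannels input channels (1 for DWI).
#' @return a list of layer specifications (the branch parameters).
#' @export
buildBranch <- function(cfg, inChannels = 1L) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  S <- cfg@convStacks; cps <- cfg@convsPerStack
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1L]] <<- ly
  addConv <- function(cin, cout) {
    add(.layerConv(cin, cout, 3L)); add(.layerBN(cout)); add(.layerReLU())
  }
  cur <- inChannels
  for (s in seq_len(S)) {                      # encoder
    for (j in seq_len(cps)) { addConv(cur, .stackWidth(cfg, s)); cur <- .stackWidth(cfg, s) }
    if (s < S) add(.layerPool(cfg@poolWindow, paste0("p", s)))
  }
  for (s in rev(seq_len(S))) {                 # decoder mirrors the encoder
    for (j in seq_len(cps)) {
      cout <- if (j == cps && s > 1L) .stackWidth(cfg, s - 1L) else .stackWidth(cfg, s)
      addConv(cur, cout); cur <- cout
    }
    if (s > 1L) add(.layerUnpool(cfg@poolWindow, paste0("p", s - 1L)))
  }
  add(.layerConv(cur, 2L, 1L))                 # 1x1 head to 2 classes
  add(.layerSoftmax())
  layers
}

# Refinement head: the input image (1 channel) concatenated with the
# ensemble probability map (2 channels), then refinementConvs 3x3
# convolutions (BN + ReLU) and a 1x1 convolution + softmax.
.buildRefine <- function(cfg) {
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1L]] <<- ly
  cur <- 3L
  for (i in seq_len(cfg@refinementConvs)) {
    add(.layerConv(cur, cfg@baseChannels, 3L))
    add(.layerBN(cfg@baseChannels)); add(.layerReLU())
    cur <- cfg@baseChannels
  }
  add(.layerConv(cur, 2L, 1L))
  add(.layerSoftmax())
  layers
}

#' Theoretical receptive field of one branch
#'
#' Side length of the input region that can influence one output pixel,
#' computed by the standard recursive composition over the branch's
#' layers: a k x k stride-1 convolution widens the field by (k - 1) x
#' jump, a pooling by (window - 1) x jump and multiplies the jump by the
#' window, and a mask-driven unpooling divides the jump back (each fine
#' pixel descends from exactly one pooled cell, so it adds no extent).
#'
#' @param cfg a [NetworkConfig-class].
#' @return receptive-field side length in pixels.
#' @export
receptiveField <- function(cfg) {
  stopifnot(is(cfg, "NetworkConfig"))
  layers <- buildBranch(cfg)
  rf <- 1; j <- 1
  for (ly in layers) {
    if (ly$type == "conv") rf <- rf + (ly$k - 1) * j
    else if (ly$type == "pool") { rf <- rf + (ly$window - 1) * j; j <- j * ly$window }
    else if (ly$type == "unpool") j <- j / ly$window
  }
  as.integer(rf)
}

#' Initialise an (untrained) ensemble encoder-decoder model
#'
#' Branch parameters are Xavier-initialised with per-branch independent
#' seeds; the diversity of their optima is what the ensemble exploits.
#'
#' @param cfg a [NetworkConfig-class].
#' @param seed integer base seed.
#' @return an [EDDModel-class] with `trained = FALSE`.
#' @export
initEDD <- function(cfg = networkConfig(), seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  branches <- lapply(seq_len(cfg@nBranches), function(i) {
    set.seed(.deriveSeed(seed, 100L + i))
    buildBranch(cfg)
  })
  set.seed(.deriveSeed(seed, 99L))
  refine <- .buildRefine(cfg)
  new("EDDModel", config = cfg, branches = branches, refine = refine,
      log = data.frame(), trained = FALSE)
}

# Full forward pass of the EDD model on a batch x (H, W, 1, N).
# Returns branch outputs, the naive ensemble h, the refined output H and
# (in training mode) all caches needed for backpropagation.
.eddForward <- function(model, x, training = FALSE) {
  N <- length(model@branches)
  bres <- vector("list", N)
  for (i in seq_len(N))
    bres[[i]] <- .netForward(model@branches[[i]], x, training)
  ps <- lapply(bres, `[[`, "out")
  h <- Reduce(`+`, ps) / N
  d <- dim(x)
  rin <- array(0, c(d[1], d[2], 3L, d[4]))
  rin[, , 1, ] <- x[, , 1, ]
  rin[, , 2:3, ] <- h
  rres <- .netForward(model@refine, rin, training)
  list(branchOut = ps, h = h, H = rres$out, bres = bres, rres = rres,
       rin = rin)
}

#' Naive ensemble forward pass
#'
#' Runs every branch on the input and fuses them by the pixel-wise
#' arithmetic mean of their softmax probability maps.
#'
#' @param model an [EDDModel-class].
#' @param x input patch or slice (matrix or (H, W, 1, N) array).
#' @return the ensemble probability array (H, W, 2, N).
#' @export
ensembleForward <- function(model, x) {
  stopifnot(is(model, "EDDModel"))
  x <- .as4d(x)
  ps <- lapply(model@branches, function(b) .netForward(b, x, FALSE)$out)
  Reduce(`+`, ps) / length(ps)
}

#' Refinement forward pass
#'
#' Concatenates the input image (1 channel) with an ensemble probability
#' map (2 channels) and applies the refinement convolutions.
#'
#' @param model an [EDDModel-class].
#' @param h ensemble probability array (H, W, 2, N).
#' @param x matching input (H, W, 1, N) array or matrix.
#' @return the refined probability array (H, W, 2, N).
#' @export
refineForward <- function(model, h, x) {
  stopifnot(is(model, "EDDModel"))
  x <- .as4d(x); h <- .as4d(h)
  if (!identical(dim(h)[c(1, 2, 4)], dim(x)[c(1, 2, 4)]))
    stop("probability map and image are not spatially congruent")
  d <- dim(x)
  rin <- array(0, c(d[1], d[2], 3L, d[4]))
  rin[, , 1, ] <- x[, , 1, ]
  rin[, , 2:3, ] <- h
  .netForward(model@refine, rin, FALSE)$out
}

#' Deeply supervised ensemble loss
#'
#' The training loss is a weighted sum of per-pixel cross-entropies of
#' the refined output, the naive ensemble, and every individual branch:
#' `lambda[1] * CE(H, y) + lambda[2] * CE(h, y) + sum_i lambda[i + 2] *
#' CE(branch_i, y)`. Probabilities are clipped to `\[1e-7, 1 - 1e-7\]`.
#'
#' @param branchOutputs list of branch probability arrays.
#' @param h,H ensemble and refined probability arrays.
#' @param y binary label array (H, W, N) or matrix.
#' @param lambda weights, length `length(branchOutputs) + 2` (a single
#'   value is recycled).
#' @return scalar loss (non-negative).
#' @export
eddLoss <- function(branchOutputs, h, H, y, lambda = 1) {
  N <- length(branchOutputs)
  lambda <- rep_len(lambda, N + 2L)
  if (is.matrix(y)) y <- array(y, c(dim(y), 1L))
  h <- .as4d(h); H <- .as4d(H)
  total <- lambda[1] * .ceProb(H, y) + lambda[2] * .ceProb(h, y)
  for (i in seq_len(N))
    total <- total + lambda[i + 2L] * .ceProb(.as4d(branchOutputs[[i]]), y)
  total
}

# In-place flip/rotation augmentation of a minibatch.
.augmentBatch <- function(x, y) {
  B <- dim(x)[4]
  fl <- runif(B) < 0.5
  rot <- sample.int(4L, B, TRUE) - 1L
  for (b in seq_len(B)) {
    a <- x[, , 1, b]; l <- y[, , b]
    if (fl[b]) { a <- a[, ncol(a):1]; l <- l[, ncol(l):1] }
    if (rot[b] > 0L) { a <- .rot90(a, rot[b]); l <- .rot90(l, rot[b]) }
    x[, , 1, b] <- a; y[, , b] <- l
  }
  list(x = x, y = y)
}

.patchDice <- function(pred, truth) {
  inter <- sum(pred * truth)
  tot <- sum(pred) + sum(truth)
  if (tot == 0) return(NA_real_)
  2 * inter / tot
}

# Forward the validation patches in chunks (eval mode) and pool a Dice
# score of the binarised refined output against the labels.
.valDice <- function(model, val, chunk = 64L) {
  n <- nPatches(val)
  if (n == 0L) return(NA_real_)
  inter <- 0; tot <- 0
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(n, at + chunk - 1L)
    x <- array(val@images[, , idx], c(dim(val@images)[1:2], 1L, length(idx)))
    y <- val@labels[, , idx, drop = FALSE]
    H <- .eddForward(model, x, training = FALSE)$H
    pred <- (H[, , 2, ] >= 0.5) * 1
    inter <- inter + sum(pred * y)
    tot <- tot + sum(pred) + sum(y)
  }
  if (tot == 0) return(NA_real_)
  2 * inter / tot
}

#' Train the ensemble encoder-decoder network
#'
#' Joint training of all branches and the refinement head by stochastic
#' gradient descent with momentum on the deeply supervised loss
#' ([eddLoss()]). Branches are Xavier-initialised with independent seeds.
#' The model returned is the one with the best validation Dice
#' (binarised refined output at 0.5); the log records per-epoch training
#' loss and validation Dice.
#'
#' @param train,val [PatchSet-class] training and validation sets.
#' @param netCfg a [NetworkConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param verbose print per-epoch progress.
#' @return a trained [EDDModel-class].
#' @export
trainEDD <- function(train, val, netCfg = networkConfig(),
                     trainCfg = trainConfig(), verbose = FALSE) {
  if (nPatches(train) == 0L) stop("training set is empty")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  model <- initEDD(netCfg, seed = trainCfg@seed)
  N <- length(model@branches)
  lambda <- rep_len(trainCfg@lambda, N + 2L)
  vel <- list(branches = lapply(model@branches, .sgdInitVelocity),
              refine = .sgdInitVelocity(model@refine))
  n <- nPatches(train)
  p <- dim(train@images)[1]
  bs <- min(trainCfg@batchSize, n)
  set.seed(.deriveSeed(trainCfg@seed, 7L))
  bestDice <- -Inf
  best <- list(branches = model@branches, refine = model@refine)
  logRows <- list()
  for (epoch in seq_len(trainCfg@maxEpochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (at in seq(1L, n, by = bs)) {
      idx <- ord[at:min(n, at + bs - 1L)]
      x <- array(train@images[, , idx], c(p, p, 1L, length(idx)))
      y <- array(train@labels[, , idx], c(p, p, length(idx)))
      if (trainCfg@augment) {
        ag <- .augmentBatch(x, y)
        x <- ag$x; y <- ag$y
      }
      fw <- .eddForward(model, x, training = TRUE)
      for (i in seq_len(N)) model@branches[[i]] <- fw$bres[[i]]$layers
      model@refine <- fw$rres$layers
      loss <- lambda[1] * .ceProb(fw$H, y) + lambda[2] * .ceProb(fw$h, y)
      for (i in seq_len(N)) loss <- loss + lambda[i + 2L] * .ceProb(fw$branchOut[[i]], y)
      if (!is.finite(loss))
        stop(sprintf("training diverged at epoch %d (loss = %s)", epoch, loss))
      epochLoss <- epochLoss + loss; nb <- nb + 1L
      # backward: refined head first, then the ensemble fan-out
      dH <- .ceProbGrad(fw$H, y, lambda[1])
      rb <- .netBackward(model@refine, fw$rres$caches, dH, needInputGrad = TRUE)
      dh <- .ceProbGrad(fw$h, y, lambda[2]) + rb$gx[, , 2:3, , drop = FALSE]
      st <- .sgdStep(model@refine, rb$grads, vel$refine, trainCfg@learningRate,
                     trainCfg@momentum, trainCfg@weightDecay)
      model@refine <- st$layers; vel$refine <- st$vel
      for (i in seq_len(N)) {
        dp <- .ceProbGrad(fw$branchOut[[i]], y, lambda[i + 2L]) + dh / N
        bb <- .netBackward(model@branches[[i]], fw$bres[[i]]$caches, dp)
        st <- .sgdStep(model@branches[[i]], bb$grads, vel$branches[[i]],
                       trainCfg@learningRate, trainCfg@momentum,
                       trainCfg@weightDecay)
        model@branches[[i]] <- st$layers; vel$branches[[i]] <- st$vel
      }
    }
    vd <- .valDice(model, val)
    logRows[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = epochLoss / nb,
                                   val_dice = vd)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val Dice %.4f", epoch,
                      epochLoss / nb, vd))
    if (!is.na(vd) && vd > bestDice) {
      bestDice <- vd
      best <- list(branches = model@branches, refine = model@refine)
    }
  }
  model@branches <- best$branches
  model@refine <- best$refine
  model@log <- do.call(rbind, logRows)
  model@trained <- TRUE
  model
}

# Reflect-pad a matrix to the given target size.
.padReflect <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  if (H2 > H) {
    extra <- m[H:(H - (H2 - H) + 1L), , drop = FALSE]
    m <- rbind(m, extra)
  }
  if (W2 > W) {
    extra <- m[, W:(W - (W2 - W) + 1L), drop = FALSE]
    m <- cbind(m, extra)
  }
  m
}

#' Segment a whole image slice
#'
#' The network is fully convolutional, so inference runs on the whole
#' slice even though training used patches. The slice is reflect-padded
#' to the next pooling-divisible size and the output cropped back.
#'
#' @param model a trained [EDDModel-class].
#' @param slice 2-d image matrix (already preprocessed).
#' @return a [ProbabilityMap-class] congruent with the slice.
#' @export
predictSlice <- function(model, slice) {
  stopifnot(is(model, "EDDModel"), is.matrix(slice))
  div <- model@config@poolWindow^(model@config@convStacks - 1L)
  H <- nrow(slice); W <- ncol(slice)
  H2 <- as.integer(ceiling(H / div) * div)
  W2 <- as.integer(ceiling(W / div) * div)
  xm <- .padReflect(slice, H2, W2)
  fw <- .eddForward(model, array(xm, c(H2, W2, 1L, 1L)), training = FALSE)
  out <- fw$H[seq_len(H), seq_len(W), , 1L, drop = FALSE]
  new("ProbabilityMap", probs = out)
}

#' Segment a whole volume slice-wise
#'
#' @param model a trained [EDDModel-class].
#' @param vol a preprocessed [DWIVolume-class].
#' @return a [ProbabilityMap-class] with one slice per volume slice.
#' @export
predictVolume <- function(model, vol) {
  stopifnot(is(vol, "DWIVolume"))
  maps <- lapply(volumeSlices(vol), function(s) probs(predictSlice(model, s)))
  d <- dim(maps[[1]])
  out <- array(0, c(d[1], d[2], 2L, length(maps)))
  for (k in seq_along(maps)) out[, , , k] <- maps[[k]][, , , 1]
  new("ProbabilityMap", probs = out)
}
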