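# Brute-force reference implementations, kept independent of the package
# internals: plain-R flood fill, set arithmetic on pixel index sets, and
# direct loops over pooling windows.

# Connected components by repeated flood fill over an explicit pixel queue.
bfLabel <- function(m, connectivity = 8L) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (m[i, j] == 0 || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        r <- p[1] + nb[d, 1]; c <- p[2] + nb[d, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] != 0 &&
            lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

bfDice <- function(x, y) {
  tot <- sum(x) + sum(y)
  if (tot == 0) return(NaN)
  2 * sum(x & y) / tot
}

# Component confusion on a single slice pair via exhaustive pairwise
# pixel-set overlap.
bfConfusion <- function(pred, gt, connectivity = 8L) {
  lp <- bfLabel(pred, connectivity); lg <- bfLabel(gt, connectivity)
  tp <- integer(0); fp <- integer(0); fn <- integer(0)
  if (max(lp) > 0) for (i in seq_len(max(lp))) {
    px <- lp == i
    if (any(px & gt > 0)) tp <- c(tp, sum(px)) else fp <- c(fp, sum(px))
  }
  if (max(lg) > 0) for (i in seq_len(max(lg))) {
    px <- lg == i
    if (!any(px & pred > 0)) fn <- c(fn, sum(px))
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Direct max pooling over explicit windows with row-major tie-breaking.
bfPool <- function(m, w) {
  Hp <- nrow(m) / w; Wp <- ncol(m) / w
  out <- matrix(0, Hp, Wp); mask <- matrix(0L, Hp, Wp)
  for (pc in seq_len(Wp)) for (pr in seq_len(Hp)) {
    best <- -Inf; besti <- 0L
    for (wr in 0:(w - 1)) for (wc in 0:(w - 1)) {
      v <- m[(pr - 1) * w + wr + 1, (pc - 1) * w + wc + 1]
      if (v > best) { best <- v; besti <- wr * w + wc }
    }
    out[pr, pc] <- best; mask[pr, pc] <- besti
  }
  list(out = out, mask = mask)
}

randomMask <- function(H, W, p = 0.3) {
  matrix(rbinom(H * W, 1, p), H, W)
}

# A small network configuration whose receptive field (32 px) equals its
# patch size, the scaled-down analogue of the full operating point.
tinyNetConfig <- function(patchSize = 32L) {
  networkConfig(convStacks = 3L, convsPerStack = 1L, baseChannels = 8L,
                patchSize = patchSize)
}

# Phantom conditions used for the network-training checks: 128 px slices,
# high lesion contrast, boundary artefacts with near-lesion brightness.
demoPhantomConfig <- function(seed = 7L, lesionContrast = 2.0) {
  phantomConfig(imageSize = 128L, nSlices = 3L, lesionCountRange = c(1L, 3L),
                lesionSizeMeanlog = log(18), lesionSizeSdlog = 0.6,
                fractionSmall = 0.6, artefactCountRange = c(2L, 4L),
                lesionContrast = lesionContrast, artefactContrast = 1.8,
                seed = seed)
}

# Cache for expensive trained models shared between test files.
.fixtureCache <- new.env(parent = emptyenv())

# Train the scaled-down two-stage cascade once per seed and memoise it.
trainedCascade <- function(seed) {
  key <- paste0("cascade", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  pcfg <- demoPhantomConfig()
  cohort <- generateCohort(pcfg, 20L)
  sets <- buildTrainingSet(cohort$subjects, patchSize = 32L, seed = 5L)
  edd <- trainEDD(sets$train, sets$val, tinyNetConfig(),
                  trainConfig(maxEpochs = 10L, seed = seed))
  valSubjects <- sets$split$subject[sets$split$set == "val"]
  res <- list(pcfg = pcfg, cohort = cohort, sets = sets, edd = edd,
              valSubjects = valSubjects)
  .fixtureCache[[key]] <- res
  res
}

# Mean subject-level Dice of the stage-1 segmentation on held-out subjects.
heldOutDice <- function(fix) {
  dices <- vapply(fix$cohort$subjects, function(s) {
    if (!(s@manifestRow$subject_id %in% fix$valSubjects)) return(NA_real_)
    vol <- normalizeIntensity(resampleInPlane(s@volume))
    mask <- binarize(predictVolume(fix$edd, vol))
    diceCoefficient(mask, s@lesionMask)
  }, numeric(1))
  mean(dices, na.rm = TRUE)
}

# Train the candidate classifier for a cascade fixture (memoised).
trainedMuscle <- function(fix, seed = 2L) {
  key <- paste0("muscle", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  trainSubjects <- fix$sets$split$subject[fix$sets$split$set == "train"]
  subs <- Filter(function(s) s@manifestRow$subject_id %in% trainSubjects,
                 fix$cohort$subjects)
  td <- dwiseg:::.muscleTrainingData(fix$edd, subs, muscleConfig())
  m <- trainMuscle(td$stacks, td$labels, muscleConfig(),
                   trainConfig(maxEpochs = 15L, seed = seed))
  .fixtureCache[[key]] <- m
  m
}
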