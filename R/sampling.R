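.emptyPatchMeta <- function() {
  data.frame(subject = character(0), slice = integer(0),
             anchor_r = integer(0), anchor_c = integer(0),
             offset_r = integer(0), offset_c = integer(0),
             aug = character(0), stringsAsFactors = FALSE)
}

.patchSet <- function(images, labels, meta) {
  new("PatchSet", images = images, labels = labels, meta = meta)
}

.bindPatchSets <- function(sets) {
  sets <- Filter(function(s) dim(s@images)[3] > 0L, sets)
  if (length(sets) == 0L) {
    ps <- 0L
    return(.patchSet(array(0, c(0, 0, 0)), array(0, c(0, 0, 0)),
                     .emptyPatchMeta()))
  }
  p <- dim(sets[[1]]@images)[1]
  n <- sum(vapply(sets, function(s) dim(s@images)[3], integer(1)))
  im <- array(0, c(p, p, n)); la <- array(0, c(p, p, n))
  at <- 0L
  for (s in sets) {
    k <- dim(s@images)[3]
    im[, , at + seq_len(k)] <- s@images
    la[, , at + seq_len(k)] <- s@labels
    at <- at + k
  }
  .patchSet(im, la, do.call(rbind, lapply(sets, function(s) s@meta)))
}

#' Number of patches in a PatchSet
#' @param x a [PatchSet-class]
#' @export
nPatches <- function(x) dim(x@images)[3]

#' Extract one training patch per lesion pixel of a slice
#'
#' Every pixel labelled as lesion anchors exactly one patch. The anchor is
#' placed at a position drawn uniformly over all patch positions, so the
#' window around it is random; regions of the window falling outside the
#' slice are zero-padded (image) and zero (label). This lesion-anchored
#' sampling rebalances the label distribution relative to whole slices,
#' where lesion pixels are a tiny minority.
#'
#' @param slice 2-d numeric image matrix.
#' @param mask congruent 2-d 0/1 matrix.
#' @param patchSize patch side in pixels (>= 8).
#' @param seed integer seed controlling the placement draws.
#' @param subject,sliceIndex provenance recorded in the patch metadata.
#' @return a [PatchSet-class] with one patch per lesion pixel (empty if
#'   the mask has none).
#' @export
extractLesionPatches <- function(slice, mask, patchSize, seed = 1L,
                                 subject = "subject", sliceIndex = 1L) {
  if (!identical(dim(slice), dim(mask)))
    stop("slice and mask must be congruent")
  if (patchSize < 8L) stop("patchSize must be >= 8")
  if (patchSize > 2L * max(dim(slice)))
    stop("patchSize larger than twice the slice side")
  anchors <- which(mask > 0, arr.ind = TRUE)
  np <- nrow(anchors)
  if (np == 0L)
    return(.patchSet(array(0, c(patchSize, patchSize, 0)),
                     array(0, c(patchSize, patchSize, 0)),
                     .emptyPatchMeta()))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.deriveSeed(seed, 17L))
  offR <- sample.int(patchSize, np, replace = TRUE) - 1L
  offC <- sample.int(patchSize, np, replace = TRUE) - 1L
  H <- nrow(slice); W <- ncol(slice)
  im <- array(0, c(patchSize, patchSize, np))
  la <- array(0, c(patchSize, patchSize, np))
  for (i in seq_len(np)) {
    r0 <- anchors[i, 1] - offR[i]          # window top-left (1-based)
    c0 <- anchors[i, 2] - offC[i]
    rs <- max(1L, r0):min(H, r0 + patchSize - 1L)
    cs <- max(1L, c0):min(W, c0 + patchSize - 1L)
    im[rs - r0 + 1L, cs - c0 + 1L, i] <- slice[rs, cs]
    la[rs - r0 + 1L, cs - c0 + 1L, i] <- mask[rs, cs]
  }
  meta <- data.frame(subject = subject, slice = as.integer(sliceIndex),
                     anchor_r = anchors[, 1], anchor_c = anchors[, 2],
                     offset_r = offR, offset_c = offC, aug = "",
                     stringsAsFactors = FALSE)
  .patchSet(im, la, meta)
}

# Rotate a matrix by k * 90 degrees counter-clockwise.
.rot90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Augment patches by horizontal flips and rotations
#'
#' Applies, per patch, a horizontal flip with probability 0.5 and a
#' rotation drawn uniformly from \{0, 90, 180, 270\} degrees. Image and
#' label are transformed congruently; right-angle rotations permute
#' pixels, so labels stay exactly binary and the lesion pixel count is
#' preserved. A continuous-angle variant (any angle, bilinear image /
#' nearest-neighbour label interpolation) is available via `continuous`.
#'
#' @param patches a [PatchSet-class].
#' @param seed integer seed.
#' @param flip,rotation optional forced values (logical / degrees),
#'   recycled over patches; when given, no random draws are made for that
#'   component.
#' @param continuous if TRUE, rotations are drawn uniformly from
#'   \[0, 360) degrees instead of right angles.
#' @return a new [PatchSet-class] with the augmentations recorded in the
#'   metadata.
#' @export
augmentPatches <- function(patches, seed = 1L, flip = NULL, rotation = NULL,
                           continuous = FALSE) {
  stopifnot(is(patches, "PatchSet"))
  np <- nPatches(patches)
  if (np == 0L) return(patches)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.deriveSeed(seed, 31L))
  fl <- if (is.null(flip)) runif(np) < 0.5 else rep_len(flip, np)
  rot <- if (is.null(rotation)) {
    if (continuous) runif(np, 0, 360) else (sample.int(4L, np, TRUE) - 1L) * 90
  } else rep_len(rotation, np)
  im <- patches@images; la <- patches@labels
  for (i in seq_len(np)) {
    a <- im[, , i]; b <- la[, , i]
    if (fl[i]) { a <- a[, ncol(a):1, drop = FALSE]; b <- b[, ncol(b):1, drop = FALSE] }
    if (rot[i] %% 90 == 0) {
      k <- as.integer(round(rot[i] / 90)) %% 4L
      a <- .rot90(a, k); b <- .rot90(b, k)
    } else {
      a <- EBImage::rotate(a, rot[i], output.dim = dim(a), filter = "bilinear")
      b <- EBImage::rotate(b, rot[i], output.dim = dim(b), filter = "none")
      b <- (b > 0.5) * 1
    }
    im[, , i] <- a; la[, , i] <- b
  }
  meta <- patches@meta
  meta$aug <- paste0(ifelse(fl, "flip+", ""), "rot", round(rot))
  .patchSet(im, la, meta)
}

#' Build subject-level train/validation patch sets
#'
#' Subjects are split (no subject contributes to both sets) with
#' `floor(n * valFraction)` validation subjects and the remainder in
#' training; patches are then extracted slice-wise from each subject's
#' normalised volume, one patch per lesion pixel.
#'
#' @param cohort list of [PhantomSubject-class], or list of
#'   `list(volume = , mask = )` pairs.
#' @param patchSize patch side in pixels.
#' @param seed integer seed (controls both the split and the placements).
#' @param valFraction fraction of subjects held out for validation.
#' @param preprocess if TRUE (default), volumes are resampled to 1.6 mm
#'   and intensity-normalised before extraction.
#' @return list with `train` and `val` [PatchSet-class] objects and
#'   `split`, a data.frame mapping subjects to sets.
#' @export
buildTrainingSet <- function(cohort, patchSize = 64L, seed = 1L,
                             valFraction = 0.3, preprocess = TRUE) {
  if (length(cohort) == 0L) stop("cohort must be non-empty")
  pairs <- lapply(cohort, function(s) {
    if (is(s, "PhantomSubject")) list(volume = s@volume, mask = s@lesionMask)
    else s
  })
  n <- length(pairs)
  nVal <- floor(n * valFraction)
  nTrain <- n - nVal
  if (nTrain < 1L || (valFraction > 0 && nVal < 1L))
    stop("fewer subjects than the requested split demands")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.deriveSeed(seed, 57L))
  ord <- sample.int(n)
  valIdx <- ord[seq_len(nVal)]
  isVal <- seq_len(n) %in% valIdx
  extractSubject <- function(i) {
    v <- pairs[[i]]$volume; m <- pairs[[i]]$mask
    if (preprocess) {
      v <- normalizeIntensity(resampleInPlane(v))
      m <- resampleInPlane(m)
    }
    sets <- lapply(seq_len(nSlices(v)), function(k) {
      extractLesionPatches(v@voxels[, , k], m@voxels[, , k], patchSize,
                           seed = .deriveSeed(seed, i * 1000L + k),
                           subject = subjectID(v), sliceIndex = k)
    })
    .bindPatchSets(sets)
  }
  train <- .bindPatchSets(lapply(which(!isVal), extractSubject))
  val <- .bindPatchSets(lapply(which(isVal), extractSubject))
  split <- data.frame(
    subject = vapply(pairs, function(p) subjectID(p$volume), character(1)),
    set = ifelse(isVal, "val", "train"), stringsAsFactors = FALSE)
  list(train = train, val = val, split = split)
}
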