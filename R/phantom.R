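#' Phantom configuration
#'
#' Builds a [PhantomConfig-class] describing a synthetic DWI-like cohort:
#' brain-shaped elliptical slices with smooth tissue texture, hyperintense
#' lesion blobs with heavy size variation (a few pixels to hundreds), and
#' bright decoy artefacts whose centroids sit in a thin ring just inside
#' the brain/air boundary, mimicking the air-interface artefacts that are
#' the dominant false-positive source in clinical DWI.
#'
#' Intensities are produced on a pre-normalisation scale (air ~ 0, brain
#' tissue ~ 1); downstream stages always apply [normalizeIntensity()], so
#' the phantom exercises the same preprocessing path as clinical data.
#'
#' @param imageSize slice side in pixels (default 128, matching a typical
#'   DWI matrix).
#' @param nSlices slices per subject (default 20).
#' @param lesionCountRange integer(2) lesions per subject.
#' @param lesionSizeMeanlog,lesionSizeSdlog log-normal parameters of the
#'   target lesion size in pixels.
#' @param fractionSmall proportion of lesions drawn with size below 37 px,
#'   the boundary of the small/large stratification.
#' @param artefactCountRange integer(2) artefacts per subject.
#' @param lesionContrast,artefactContrast intensity offsets added to
#'   lesion/artefact pixels, in units of the tissue intensity.
#' @param noiseSd additive Gaussian noise level.
#' @param seed integer base seed for the cohort.
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(imageSize = 128L, nSlices = 20L,
                          lesionCountRange = c(1L, 5L),
                          lesionSizeMeanlog = log(20), lesionSizeSdlog = 0.9,
                          fractionSmall = 0.75,
                          artefactCountRange = c(2L, 6L),
                          lesionContrast = 1.0, artefactContrast = 0.9,
                          noiseSd = 0.08, seed = 42L) {
  new("PhantomConfig", imageSize = as.integer(imageSize),
      nSlices = as.integer(nSlices),
      lesionCountRange = as.integer(lesionCountRange),
      lesionSizeMeanlog = lesionSizeMeanlog,
      lesionSizeSdlog = lesionSizeSdlog,
      fractionSmall = fractionSmall,
      artefactCountRange = as.integer(artefactCountRange),
      lesionContrast = lesionContrast, artefactContrast = artefactContrast,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# Normalised elliptical radius of every pixel: 1 on the brain boundary.
.ellipseRho <- function(H, W, cx, cy, a, b, theta) {
  r <- matrix(seq_len(H), H, W) - cx
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  u <- r * cos(theta) + c_ * sin(theta)
  v <- -r * sin(theta) + c_ * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

# An irregular blob: the union of 1-3 rotated ellipses, rescaled until its
# pixel count satisfies the size-class bounds. Returns an integer matrix
# (n x 2) of pixel offsets relative to the blob centroid.
.makeBlob <- function(target, minSize, maxSize) {
  nEll <- sample.int(3L, 1L)
  q <- runif(1, 0.45, 1)
  a0 <- sqrt(target / (pi * q)); b0 <- a0 * q
  th0 <- runif(1, 0, pi)
  extra <- if (nEll > 1L) lapply(seq_len(nEll - 1L), function(i) {
    list(dr = runif(1, -0.7, 0.7) * a0, dc = runif(1, -0.7, 0.7) * b0,
         a = a0 * runif(1, 0.35, 0.7), b = b0 * runif(1, 0.35, 0.7),
         th = runif(1, 0, pi))
  }) else list()
  raster <- function(s) {
    ext <- ceiling(2.2 * a0 * s) + 3L
    cx <- ext / 2; cy <- ext / 2
    m <- .ellipseRho(ext, ext, cx, cy, a0 * s, b0 * s, th0) <= 1
    for (e in extra)
      m <- m | (.ellipseRho(ext, ext, cx + e$dr * s, cy + e$dc * s,
                            e$a * s, e$b * s, e$th) <= 1)
    m
  }
  s <- 1
  m <- raster(s)
  for (i in 1:40) {
    n <- sum(m)
    if (n > maxSize) s <- s * 0.92
    else if (n < minSize) s <- s * 1.1
    else break
    m <- raster(s)
  }
  px <- which(m, arr.ind = TRUE)
  px[, 1] <- px[, 1] - round(mean(px[, 1]))
  px[, 2] <- px[, 2] - round(mean(px[, 2]))
  px
}

# Deterministic per-subject seed below 2^31, derived from the cohort seed.
.deriveSeed <- function(base, k) {
  as.integer((((abs(base) %% 1000003) * 10007 + (k %% 100003) * 101 + 7)
              %% 2147483647))
}

#' Generate one phantom subject
#'
#' The brain is a fixed ellipse shared across slices with smoothed tissue
#' texture. Each lesion is a union of 1-3 random ellipses placed in the
#' brain interior with its intensity raised by `lesionContrast`; artefacts
#' are similar blobs whose centroids lie within a thin ring just inside
#' the brain boundary (centroid distance from the boundary at most 10% of
#' the semi-minor axis) and are excluded from the ground-truth mask.
#' Lesion and artefact components are pairwise disjoint. Output is
#' bit-identical for a given `(cfg@seed, subjectSeed)` pair.
#'
#' @param cfg a [PhantomConfig-class].
#' @param subjectSeed integer per-subject seed.
#' @return a [PhantomSubject-class].
#' @export
generateSubject <- function(cfg, subjectSeed) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.deriveSeed(cfg@seed, subjectSeed))

  n <- cfg@imageSize; ns <- cfg@nSlices
  cx <- n / 2 + runif(1, -2, 2); cy <- n / 2 + runif(1, -2, 2)
  a <- 0.42 * n * runif(1, 0.95, 1.05)
  b <- 0.34 * n * runif(1, 0.95, 1.05)
  th <- runif(1, -0.2, 0.2)
  rho <- .ellipseRho(n, n, cx, cy, a, b, th)
  brain <- rho <= 1
  brainArea <- sum(brain)
  bmin <- min(a, b)

  vol <- array(0, c(n, n, ns))
  lmask <- array(0, c(n, n, ns))
  amask <- array(0, c(n, n, ns))

  drawTarget <- function() {
    small <- runif(1) < cfg@fractionSmall
    for (i in 1:50) {
      t <- rlnorm(1, cfg@lesionSizeMeanlog, cfg@lesionSizeSdlog)
      if (small && t < 37) return(list(t = max(t, 4), small = TRUE))
      if (!small && t >= 37) return(list(t = t, small = FALSE))
    }
    if (small) list(t = runif(1, 4, 36), small = TRUE)
    else list(t = runif(1, 37, 150), small = FALSE)
  }

  placeBlob <- function(px, slice, zone, occupied) {
    # zone: function(rhoCentroid, rhoPixels) -> TRUE if placement legal.
    # A 1-pixel halo must also be free so that separate objects never
    # merge into one connected component.
    halo <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    for (i in 1:200) {
      r0 <- sample.int(n, 1L); c0 <- sample.int(n, 1L)
      rr <- px[, 1] + r0; cc <- px[, 2] + c0
      if (any(rr < 2 | rr > n - 1L | cc < 2 | cc > n - 1L)) next
      idx <- cbind(rr, cc)
      if (!zone(rho[r0, c0], rho[idx])) next
      hr <- rep(rr, each = 9L) + halo[, 1]
      hc <- rep(cc, each = 9L) + halo[, 2]
      if (any(occupied[cbind(hr, hc)] != 0)) next
      return(idx)
    }
    NULL
  }

  rint <- function(rg) if (rg[1] >= rg[2]) rg[1] else
    sample(seq(rg[1], rg[2]), 1L)
  nles <- rint(cfg@lesionCountRange)
  lesionSizes <- integer(0)
  for (j in seq_len(nles)) {
    tg <- drawTarget()
    if (tg$t > 0.5 * brainArea)
      stop("requested lesion larger than the brain region")
    bounds <- if (tg$small) c(3, 36) else c(37, floor(0.3 * brainArea))
    px <- .makeBlob(tg$t, bounds[1], bounds[2])
    sl <- sample.int(ns, 1L)
    occ <- lmask[, , sl] + amask[, , sl]
    idx <- placeBlob(px, sl, function(rc, rp) all(rp <= 0.85), occ)
    if (is.null(idx)) next
    sl_m <- lmask[, , sl]; sl_m[idx] <- 1; lmask[, , sl] <- sl_m
    lesionSizes <- c(lesionSizes, nrow(idx))
  }

  nart <- rint(cfg@artefactCountRange)
  for (j in seq_len(nart)) {
    t <- min(max(rlnorm(1, log(9), 0.5), 3), 30)
    px <- .makeBlob(t, 3, 30)
    sl <- sample.int(ns, 1L)
    occ <- lmask[, , sl] + amask[, , sl]
    # centroid within 10% of the semi-minor axis from the boundary,
    # pixels clipped to the brain
    idx <- placeBlob(px, sl,
                     function(rc, rp) rc >= 0.9 && rc <= 0.99 && all(rp <= 1),
                     occ)
    if (is.null(idx)) next
    sl_m <- amask[, , sl]; sl_m[idx] <- 1; amask[, , sl] <- sl_m
  }

  for (k in seq_len(ns)) {
    tex <- EBImage::gblur(matrix(rnorm(n * n), n, n), sigma = 2)
    tex <- 0.08 * tex / max(sd(tex), 1e-8)
    sl <- ifelse(brain, 1 + tex, 0.02)
    sl <- sl + cfg@lesionContrast * lmask[, , k] +
      cfg@artefactContrast * amask[, , k]
    sl <- sl + cfg@noiseSd * matrix(rnorm(n * n), n, n)
    vol[, , k] <- sl
  }

  meanSize <- if (length(lesionSizes)) mean(lesionSizes) else NA_real_
  cls <- if (is.na(meanSize)) NA_character_
         else if (meanSize < 37) "small" else "large"
  sid <- sprintf("S%04d", subjectSeed)
  mrow <- data.frame(subject_id = sid, n_lesions = length(lesionSizes),
                     mean_size = meanSize, class = cls, seed = subjectSeed,
                     stringsAsFactors = FALSE)
  new("PhantomSubject",
      volume = DWIVolume(vol, c(1.6, 1.6), 5, sid),
      lesionMask = LesionMask(lmask, c(1.6, 1.6), 5, sid),
      artefactMask = LesionMask(amask, c(1.6, 1.6), 5, sid),
      manifestRow = mrow)
}

#' Generate a phantom cohort
#'
#' Subject seeds are derived deterministically from the cohort seed, so
#' two cohorts generated from the same configuration are identical.
#'
#' @param cfg a [PhantomConfig-class].
#' @param nSubjects number of subjects (>= 1).
#' @param firstSeed subject seed of the first subject (default 1);
#'   subsequent subjects use consecutive seeds, so disjoint cohorts can be
#'   drawn from one configuration by offsetting.
#' @return list with `subjects` (list of [PhantomSubject-class]) and
#'   `manifest` (data.frame).
#' @export
generateCohort <- function(cfg, nSubjects, firstSeed = 1L) {
  stopifnot(is(cfg, "PhantomConfig"))
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  subjects <- lapply(seq_len(nSubjects) + firstSeed - 1L,
                     function(k) generateSubject(cfg, k))
  manifest <- do.call(rbind, lapply(subjects, function(s) s@manifestRow))
  list(subjects = subjects, manifest = manifest)
}

#' Per-component lesion sizes and subject mean size
#'
#' Components are labelled slice-wise with the shared 8-connectivity
#' convention. An empty mask yields an empty size vector and an undefined
#' (NA) mean, flagged by `defined = FALSE`.
#'
#' @param mask a [LesionMask-class].
#' @param connectivity 4 or 8 (default 8).
#' @return list with `sizes`, `meanSize`, `class` ("small" if the mean is
#'   below 37 px, else "large") and `defined`.
#' @export
lesionSizeStats <- function(mask, connectivity = 8L) {
  stopifnot(is(mask, "LesionMask"))
  sizes <- integer(0)
  for (k in seq_len(nSlices(mask))) {
    lab <- label_components(matrix(as.integer(mask@voxels[, , k]),
                                   nrow(mask@voxels)), connectivity)
    if (max(lab) > 0L) sizes <- c(sizes, tabulate(lab[lab > 0L]))
  }
  if (length(sizes) == 0L)
    return(list(sizes = integer(0), meanSize = NA_real_,
                class = NA_character_, defined = FALSE))
  m <- mean(sizes)
  list(sizes = sizes, meanSize = m,
       class = if (m < 37) "small" else "large", defined = TRUE)
}

#' Write a phantom cohort to disk
#'
#' Emits one NIfTI image/mask pair per subject plus a CSV manifest
#' (subject_id, n_lesions, mean_size, class, seed).
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    sid <- s@manifestRow$subject_id
    writeVolume(s@volume, file.path(dir, paste0(sid, "_dwi.nii.gz")))
    writeVolume(s@lesionMask, file.path(dir, paste0(sid, "_mask.nii.gz")))
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mp, row.names = FALSE)
  invisible(mp)
}
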