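#' Construct a DWIVolume or LesionMask
#'
#' @param voxels 3-d numeric array (rows x columns x slices).
#' @param inPlaneSpacing numeric(2) in-plane pixel size in mm.
#' @param sliceSpacing slice spacing in mm.
#' @param subjectID subject identifier.
#' @return a [DWIVolume-class].
#' @export
DWIVolume <- function(voxels, inPlaneSpacing = c(1.6, 1.6), sliceSpacing = 5,
                      subjectID = "subject") {
  new("DWIVolume", voxels = voxels,
      inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing), subjectID = subjectID)
}

#' @rdname DWIVolume
#' @return for `LesionMask()`, a [LesionMask-class]; values are binarised
#'   by `value > 0`.
#' @export
LesionMask <- function(voxels, inPlaneSpacing = c(1.6, 1.6), sliceSpacing = 5,
                       subjectID = "subject") {
  if (!all(is.finite(voxels)))
    stop("mask contains non-finite values")
  v <- array(as.numeric(voxels > 0), dim = dim(voxels))
  new("LesionMask", voxels = v,
      inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing), subjectID = subjectID)
}

#' Read a DWI volume or lesion mask from NIfTI
#'
#' In-plane and slice spacing are taken from the header pixdim fields.
#' Mask files are binarised by `value > 0`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"image"` or `"mask"`.
#' @param subjectID optional identifier; defaults to the file stem.
#' @return a [DWIVolume-class] or [LesionMask-class].
#' @export
readVolume <- function(path, kind = c("image", "mask"), subjectID = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) != 3L)
    stop("expected a 3-d volume, got ", length(dim(a)), "-d data in ", path)
  pd <- RNifti::pixdim(img)
  if (is.null(subjectID))
    subjectID <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (kind == "image") {
    DWIVolume(a, inPlaneSpacing = pd[1:2], sliceSpacing = pd[3],
              subjectID = subjectID)
  } else {
    LesionMask(a, inPlaneSpacing = pd[1:2], sliceSpacing = pd[3],
               subjectID = subjectID)
  }
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit \{0, 1\}; images as 32-bit float.
#'
#' @param vol a [DWIVolume-class] or [LesionMask-class].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- c(vol@inPlaneSpacing, vol@sliceSpacing)
  dt <- if (is(vol, "LesionMask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Resample a volume in-plane to a uniform pixel size
#'
#' Every slice is resampled independently in 2-d to the target spacing
#' (default 1.6 mm); the slice axis is never resampled because the
#' acquisitions are strongly anisotropic and interpolating across thick
#' slices would introduce errors. Images are interpolated bilinearly,
#' masks by nearest neighbour (so mask values stay in \{0, 1\}). The
#' output grid size per axis is `round(extent_mm / target)`.
#'
#' @param vol a [DWIVolume-class] or [LesionMask-class].
#' @param targetSpacing target in-plane pixel size in mm (default 1.6).
#' @return a volume of the same class at the target spacing.
#' @export
resampleInPlane <- function(vol, targetSpacing = 1.6) {
  stopifnot(is(vol, "DWIVolume"))
  if (!is.numeric(targetSpacing) || length(targetSpacing) != 1L ||
      targetSpacing <= 0)
    stop("targetSpacing must be a single positive value (mm)")
  src <- vol@inPlaneSpacing
  d <- dim(vol@voxels)
  if (max(abs(src - targetSpacing)) < 1e-9) {
    out <- vol
    out@inPlaneSpacing <- c(targetSpacing, targetSpacing)
    return(out)
  }
  newH <- max(1L, as.integer(round(d[1] * src[1] / targetSpacing)))
  newW <- max(1L, as.integer(round(d[2] * src[2] / targetSpacing)))
  filt <- if (is(vol, "LesionMask")) "none" else "bilinear"
  nv <- array(0, c(newH, newW, d[3]))
  for (k in seq_len(d[3]))
    nv[, , k] <- EBImage::resize(vol@voxels[, , k], w = newH, h = newW,
                                 filter = filt)
  out <- vol
  out@voxels <- nv
  out@inPlaneSpacing <- c(targetSpacing, targetSpacing)
  validObject(out)
  out
}

#' Normalise voxel intensities to zero mean and unit variance
#'
#' Statistics are computed over all voxels of the 3-d volume (per
#' subject), so all slices of one subject share a common intensity scale.
#' The population standard deviation is used, so the normalised volume has
#' mean exactly 0 and standard deviation exactly 1.
#'
#' @param vol a [DWIVolume-class].
#' @return the normalised volume.
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "DWIVolume"))
  v <- vol@voxels
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s < 1e-12)
    stop("degenerate input: constant volume has zero variance")
  out <- vol
  out@voxels <- (v - mu) / s
  out
}

#' Iterate over the 2-d slices of a volume
#'
#' @param vol a [DWIVolume-class].
#' @return a list of matrices in ascending slice order; each carries an
#'   `index` attribute with its slice index.
#' @export
volumeSlices <- function(vol) {
  stopifnot(is(vol, "DWIVolume"))
  lapply(seq_len(nSlices(vol)), function(i) {
    s <- vol@voxels[, , i]
    attr(s, "index") <- i
    s
  })
}
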