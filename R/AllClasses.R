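#' @import methods
#' @importFrom stats rnorm runif rlnorm sd
#' @importFrom Rcpp evalCpp
#' @useDynLib dwiseg, .registration = TRUE
NULL

#' DWIVolume: a 3-d diffusion-weighted image volume
#'
#' A stack of 2-d axial slices with in-plane spacing metadata. Voxels are
#' stored as a numeric array with dimensions (rows, columns, slices);
#' acquisitions are strongly anisotropic (thick slices), so all image
#' analysis in this package is carried out slice-wise in 2-d and the slice
#' axis is never resampled.
#'
#' @slot voxels numeric 3-d array (rows x columns x slices) of intensities.
#' @slot inPlaneSpacing numeric(2), in-plane pixel size in mm (row, column).
#' @slot sliceSpacing numeric(1), slice spacing in mm.
#' @slot subjectID character(1) identifier.
#' @export
setClass("DWIVolume",
  representation(voxels = "array", inPlaneSpacing = "numeric",
                 sliceSpacing = "numeric", subjectID = "character"),
  prototype(inPlaneSpacing = c(1.6, 1.6), sliceSpacing = 5,
            subjectID = "subject"))

setValidity("DWIVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3-d array")
  if (dim(v)[3] < 1L) return("volume must contain at least one slice")
  if (length(object@inPlaneSpacing) != 2L || any(object@inPlaneSpacing <= 0))
    return("inPlaneSpacing must be two positive values (mm)")
  if (!all(is.finite(v))) return("voxel intensities must be finite")
  TRUE
})

#' LesionMask: a binary annotation volume
#'
#' Same geometry as its paired [DWIVolume-class]; voxel values are 0/1.
#'
#' @slot voxels numeric 3-d array with values in \{0, 1\}.
#' @slot inPlaneSpacing,sliceSpacing,subjectID as in [DWIVolume-class].
#' @export
setClass("LesionMask", contains = "DWIVolume")

setValidity("LesionMask", function(object) {
  v <- object@voxels
  if (!all(v %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' ProbabilityMap: per-pixel two-class lesion probabilities
#'
#' Background and lesion probabilities for each pixel of one or more
#' slices, stored as (rows, columns, 2, slices). Channel 1 is background,
#' channel 2 is lesion; the two must sum to one at every pixel.
#'
#' @slot probs numeric 4-d array (rows x columns x 2 x slices).
#' @export
setClass("ProbabilityMap", representation(probs = "array"))

setValidity("ProbabilityMap", function(object) {
  p <- object@probs
  if (length(dim(p)) != 4L || dim(p)[3] != 2L)
    return("probs must be a 4-d array with 2 class channels")
  if (any(p < -1e-8) || any(p > 1 + 1e-8))
    return("probabilities must lie in [0, 1]")
  s <- p[, , 1L, , drop = FALSE] + p[, , 2L, , drop = FALSE]
  if (max(abs(s - 1)) > 1e-5)
    return("class probabilities must sum to 1 per pixel")
  TRUE
})

#' PoolingMask: recorded max-activation locations
#'
#' For every pooled cell and channel, the within-window location of the
#' maximal activation, encoded as a 0-based row-major index
#' `wr * window + wc`. These masks invert pooling during decoding: the
#' unpooling layer scatters each pooled value back to its recorded
#' position.
#'
#' @slot index integer 4-d array congruent with the pooled map.
#' @slot window integer(1) pooling window side.
#' @export
setClass("PoolingMask",
  representation(index = "array", window = "integer"))

setValidity("PoolingMask", function(object) {
  if (length(dim(object@index)) != 4L) return("index must be a 4-d array")
  w <- object@window
  if (length(w) != 1L || w < 2L) return("window must be a single integer >= 2")
  if (any(object@index < 0L) || any(object@index >= w * w))
    return("recorded locations must lie inside their window")
  TRUE
})

#' PatchSet: a set of paired image/label training patches
#'
#' The training unit of the segmentation networks: square image patches
#' paired with binary label patches, one patch per lesion pixel, together
#' with provenance metadata (subject, slice, anchor pixel, in-patch
#' placement offset, augmentations applied).
#'
#' @slot images numeric array (patch x patch x n).
#' @slot labels numeric array (patch x patch x n) with values 0/1.
#' @slot meta data.frame with one row per patch: subject, slice, anchor
#'   row/column (1-based slice coordinates), offset row/column (0-based
#'   in-patch position of the anchor), augmentations applied.
#' @export
setClass("PatchSet",
  representation(images = "array", labels = "array", meta = "data.frame"))

setValidity("PatchSet", function(object) {
  di <- dim(object@images); dl <- dim(object@labels)
  if (!identical(di, dl)) return("image and label arrays must be congruent")
  if (length(di) != 3L || di[1] != di[2]) return("patches must be square")
  if (nrow(object@meta) != di[3]) return("meta must have one row per patch")
  if (!all(object@labels %in% c(0, 1))) return("labels must be 0/1")
  TRUE
})

#' CandidateLesion: one connected component of a binarised map
#'
#' @slot id integer candidate identifier (unique within a subject).
#' @slot pixels integer matrix (n x 3) of (slice, row, col), 1-based.
#' @slot size integer pixel count.
#' @slot centroid numeric(2) (row, col) centroid on its slice.
#' @slot bbox integer(4) (rmin, cmin, rmax, cmax).
#' @slot slice integer slice index.
#' @slot meanProb numeric mean lesion probability over the component.
#' @export
setClass("CandidateLesion",
  representation(id = "integer", pixels = "matrix", size = "integer",
                 centroid = "numeric", bbox = "integer", slice = "integer",
                 meanProb = "numeric"))

setValidity("CandidateLesion", function(object) {
  if (nrow(object@pixels) != object@size)
    return("size must equal the number of pixels")
  if (object@size < 1L) return("candidate must contain at least one pixel")
  bb <- object@bbox
  px <- object@pixels
  if (any(px[, 2] < bb[1]) || any(px[, 2] > bb[3]) ||
      any(px[, 3] < bb[2]) || any(px[, 3] > bb[4]))
    return("bounding box must contain all pixels")
  TRUE
})

#' PhantomConfig: parameters of the synthetic DWI phantom
#'
#' Controls the simulated cohort: brain-shaped slices, hyperintense lesion
#' components with heavy size variation, and bright decoy artefacts near
#' the brain/air boundary that mimic small lesions.
#'
#' @slot imageSize integer pixels per slice side.
#' @slot nSlices integer slices per subject.
#' @slot lesionCountRange integer(2) min/max lesions per subject.
#' @slot lesionSizeMeanlog,lesionSizeSdlog log-normal size parameters (px).
#' @slot fractionSmall numeric in \[0,1\]: proportion of lesions drawn with
#'   target size below 37 px (the small/large stratification boundary).
#' @slot artefactCountRange integer(2) min/max artefacts per subject.
#' @slot lesionContrast,artefactContrast positive intensity offsets, in
#'   units of the brain tissue intensity (tissue ~ 1, air ~ 0).
#' @slot noiseSd additive Gaussian noise level (same units).
#' @slot seed integer base seed of the cohort.
#' @export
setClass("PhantomConfig",
  representation(imageSize = "integer", nSlices = "integer",
                 lesionCountRange = "integer",
                 lesionSizeMeanlog = "numeric", lesionSizeSdlog = "numeric",
                 fractionSmall = "numeric", artefactCountRange = "integer",
                 lesionContrast = "numeric", artefactContrast = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (object@imageSize < 32L) return("imageSize must be >= 32")
  if (object@nSlices < 1L) return("nSlices must be >= 1")
  if (any(object@lesionCountRange < 0L) || any(object@artefactCountRange < 0L))
    return("object counts must be >= 0")
  if (object@lesionCountRange[1] > object@lesionCountRange[2] ||
      object@artefactCountRange[1] > object@artefactCountRange[2])
    return("count ranges must be (min, max) with min <= max")
  if (object@lesionContrast <= 0 || object@artefactContrast <= 0)
    return("contrasts must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@fractionSmall < 0 || object@fractionSmall > 1)
    return("fractionSmall must lie in [0, 1]")
  TRUE
})

#' PhantomSubject: one simulated subject
#'
#' @slot volume the raw (pre-normalisation) [DWIVolume-class].
#' @slot lesionMask ground-truth [LesionMask-class] (lesions only).
#' @slot artefactMask decoy components, excluded from the ground truth;
#'   disjoint from `lesionMask` by construction.
#' @slot manifestRow one-row data.frame: subject_id, n_lesions, mean_size,
#'   class ("small"/"large"), seed.
#' @export
setClass("PhantomSubject",
  representation(volume = "DWIVolume", lesionMask = "LesionMask",
                 artefactMask = "LesionMask", manifestRow = "data.frame"))

setValidity("PhantomSubject", function(object) {
  if (any(object@lesionMask@voxels * object@artefactMask@voxels != 0))
    return("lesion and artefact masks must be disjoint")
  TRUE
})

#' NetworkConfig: architecture of one encoder-decoder branch
#'
#' The encoder is `convStacks` stacks of `convsPerStack` 3x3 stride-1
#' convolutions (batch normalisation + ReLU after each), with a
#' mask-recording 2x2 max pooling between consecutive stacks. The decoder
#' mirrors the encoder, with unpooling layers consuming the corresponding
#' pooling masks, followed by a 1x1 convolution to 2 classes and a
#' per-pixel softmax. Channel width starts at `baseChannels` and doubles
#' at each pooling.
#'
#' @slot nBranches integer number of ensemble branches (default 2).
#' @slot convStacks integer encoder stacks (default 3: two poolings).
#' @slot convsPerStack integer convolutions per stack (default 2).
#' @slot baseChannels integer first-stack width (default 32).
#' @slot patchSize integer training patch side in pixels (default 64).
#' @slot poolWindow integer pooling window (default 2).
#' @slot refinementConvs integer 3x3 convolutions in the refinement head
#'   (default 3).
#' @export
setClass("NetworkConfig",
  representation(nBranches = "integer", convStacks = "integer",
                 convsPerStack = "integer", baseChannels = "integer",
                 patchSize = "integer", poolWindow = "integer",
                 refinementConvs = "integer"))

setValidity("NetworkConfig", function(object) {
  if (object@convStacks < 2L) return("convStacks must be >= 2")
  if (object@nBranches < 1L) return("nBranches must be >= 1")
  if (object@convsPerStack < 1L) return("convsPerStack must be >= 1")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (object@poolWindow < 2L) return("poolWindow must be >= 2")
  if (object@patchSize < 8L) return("patchSize must be >= 8")
  if (object@refinementConvs < 1L) return("refinementConvs must be >= 1")
  TRUE
})

#' TrainConfig: optimisation hyperparameters
#'
#' Stochastic gradient descent with momentum; Xavier weight initialisation.
#' Defaults follow the fixed operating point used for lesion segmentation:
#' learning rate 0.05, momentum 0.9, weight decay 0, all loss weights 1.
#'
#' @slot learningRate numeric > 0.
#' @slot momentum numeric in [0, 1).
#' @slot weightDecay numeric >= 0.
#' @slot lambda numeric loss weights (length N + 2 for an N-branch
#'   ensemble; recycled if a single value is given).
#' @slot batchSize integer minibatch size.
#' @slot maxEpochs integer training epochs.
#' @slot seed integer RNG seed.
#' @slot augment logical: apply flip/rotation augmentation per minibatch.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 weightDecay = "numeric", lambda = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 seed = "integer", augment = "logical"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (any(object@lambda < 0)) return("loss weights must be >= 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum must lie in [0, 1)")
  if (object@batchSize < 1L || object@maxEpochs < 1L)
    return("batchSize and maxEpochs must be >= 1")
  TRUE
})

#' MuscleConfig: candidate evaluation stage parameters
#'
#' @slot threshold numeric binarisation threshold in (0, 1) (default 0.5).
#' @slot smallObjectLimit integer: components of at most this many pixels
#'   are sent to the candidate classifier; larger components bypass it
#'   (default 60 px, below which essentially all false positives fall).
#' @slot connectivity integer 4 or 8 (default 8, 2-d slice-wise).
#' @slot outputSide integer side of the resized multi-scale patches
#'   (default 16).
#' @slot convChannels integer(4) channels of the four convolutions.
#' @slot fcWidths integer(3) widths of the three fully connected layers.
#' @export
setClass("MuscleConfig",
  representation(threshold = "numeric", smallObjectLimit = "integer",
                 connectivity = "integer", outputSide = "integer",
                 convChannels = "integer", fcWidths = "integer"))

setValidity("MuscleConfig", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie strictly inside (0, 1)")
  if (object@smallObjectLimit < 1L) return("smallObjectLimit must be >= 1")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (length(object@convChannels) != 4L) return("convChannels must have length 4")
  if (length(object@fcWidths) != 3L) return("fcWidths must have length 3")
  if (object@fcWidths[3] != 2L) return("the last FC layer must have 2 outputs")
  TRUE
})

#' EDDModel: a trained (or initialised) ensemble encoder-decoder network
#'
#' @slot config [NetworkConfig-class] used to build the model.
#' @slot branches list of per-branch parameter lists.
#' @slot refine parameter list of the refinement head.
#' @slot log data.frame with per-epoch training loss and validation Dice.
#' @slot trained logical.
#' @export
setClass("EDDModel",
  representation(config = "NetworkConfig", branches = "list",
                 refine = "list", log = "data.frame", trained = "logical"))

#' MuscleModel: a trained candidate-evaluation network
#'
#' @slot config [MuscleConfig-class].
#' @slot params parameter list of the network.
#' @slot log data.frame per-epoch loss/accuracy log.
#' @slot trained logical.
#' @export
setClass("MuscleModel",
  representation(config = "MuscleConfig", params = "list",
                 log = "data.frame", trained = "logical"))

#' EvalReport: per-subject and cohort-aggregated metrics
#'
#' @slot subjects data.frame, one row per subject: dice, n_fp, n_fn,
#'   has_tp, mean_gt_size.
#' @slot summary data.frame with the cohort aggregates: mean Dice, mean
#'   number of false-positive components (m#FP) and false negatives
#'   (m#FN), mean pixel size of false positives (mSFP) and false
#'   negatives (mSFN, both pooled across subjects), and the detection
#'   rate DR (fraction of subjects with at least one true-positive
#'   component).
#' @slot fpSizes,fnSizes integer vectors of all FP/FN component sizes
#'   pooled across the cohort.
#' @export
setClass("EvalReport",
  representation(subjects = "data.frame", summary = "data.frame",
                 fpSizes = "integer", fnSizes = "integer"))
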