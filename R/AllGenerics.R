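#' @rdname DWIVolume-class
#' @param object,x a `DWIVolume` or derived object
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname DWIVolume-class
#' @export
setGeneric("inPlaneSpacing", function(x) standardGeneric("inPlaneSpacing"))

#' @rdname DWIVolume-class
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' @rdname DWIVolume-class
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname DWIVolume-class
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname DWIVolume-class
#' @param i slice index (1-based)
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @rdname ProbabilityMap-class
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @export
#' @rdname DWIVolume-class
setMethod("voxels", "DWIVolume", function(x) x@voxels)

#' @export
#' @rdname DWIVolume-class
setMethod("inPlaneSpacing", "DWIVolume", function(x) x@inPlaneSpacing)

#' @export
#' @rdname DWIVolume-class
setMethod("sliceSpacing", "DWIVolume", function(x) x@sliceSpacing)

#' @export
#' @rdname DWIVolume-class
setMethod("subjectID", "DWIVolume", function(x) x@subjectID)

#' @export
#' @rdname DWIVolume-class
setMethod("nSlices", "DWIVolume", function(x) dim(x@voxels)[3])

#' @export
#' @rdname DWIVolume-class
setMethod("getSlice", "DWIVolume", function(x, i) {
  stopifnot(i >= 1L, i <= nSlices(x))
  x@voxels[, , i]
})

#' @export
#' @rdname ProbabilityMap-class
setMethod("probs", "ProbabilityMap", function(x) x@probs)

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s '%s': %d x %d x %d voxels, %.2f x %.2f mm in-plane, %.1f mm slices\n",
              class(object), object@subjectID, d[1], d[2], d[3],
              object@inPlaneSpacing[1], object@inPlaneSpacing[2],
              object@sliceSpacing))
  invisible(NULL)
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityMap: %d x %d pixels, %d slice(s); lesion prob range [%.3f, %.3f]\n",
              d[1], d[2], d[4], min(object@probs[, , 2, ]),
              max(object@probs[, , 2, ])))
  invisible(NULL)
})

setMethod("show", "PatchSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("PatchSet: %d patches of %d x %d px from %d subject(s)\n",
              d[3], d[1], d[2], length(unique(object@meta$subject))))
  invisible(NULL)
})

setMethod("show", "CandidateLesion", function(object) {
  cat(sprintf("CandidateLesion #%d: %d px on slice %d, centroid (%.1f, %.1f), mean prob %.3f\n",
              object@id, object@size, object@slice,
              object@centroid[1], object@centroid[2], object@meanProb))
  invisible(NULL)
})

setMethod("show", "EDDModel", function(object) {
  cfg <- object@config
  cat(sprintf("EDDModel: %d branch(es), %d stacks x %d convs, base %d channels; %s\n",
              cfg@nBranches, cfg@convStacks, cfg@convsPerStack,
              cfg@baseChannels,
              if (object@trained) "trained" else "untrained"))
  invisible(NULL)
})

setMethod("show", "MuscleModel", function(object) {
  cat(sprintf("MuscleModel (4 convs, 1 pool, 3 FC): %s\n",
              if (object@trained) "trained" else "untrained"))
  invisible(NULL)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport over", nrow(object@subjects), "subject(s)\n")
  print(object@summary, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject '%s': %d lesion(s), mean size %.1f px (%s)\n",
              object@manifestRow$subject_id, object@manifestRow$n_lesions,
              object@manifestRow$mean_size, object@manifestRow$class))
  invisible(NULL)
})
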