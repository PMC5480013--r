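#' Dice coefficient between two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)`, computed over the whole 3-d
#' subject. When both masks are empty the overlap is undefined and `NaN`
#' is returned (callers treat it as a flagged undefined value).
#'
#' @param X,Y congruent [LesionMask-class] objects or binary arrays.
#' @return Dice coefficient in \[0, 1\], or `NaN` if both masks are empty.
#' @export
diceCoefficient <- function(X, Y) {
  x <- if (is(X, "LesionMask")) X@voxels else X
  y <- if (is(Y, "LesionMask")) Y@voxels else Y
  if (!identical(dim(x), dim(y))) stop("masks must be congruent")
  tot <- sum(x) + sum(y)
  if (tot == 0) return(NaN)
  2 * sum(x * y) / tot
}

#' Component-level confusion between prediction and ground truth
#'
#' Components are labelled slice-wise in 2-d with the shared
#' connectivity convention. A predicted component is a true positive if
#' it overlaps the ground truth in at least one pixel, otherwise a false
#' positive; a ground-truth component is a false negative if it overlaps
#' the prediction in zero pixels. Sizes are in pixels.
#'
#' @param pred,gt congruent [LesionMask-class] objects or binary arrays.
#' @param connectivity 4 or 8 (default 8).
#' @return list with `tp`, `fp`, `fn`: data.frames of (slice, size).
#' @export
componentConfusion <- function(pred, gt, connectivity = 8L) {
  p <- if (is(pred, "LesionMask")) pred@voxels else pred
  g <- if (is(gt, "LesionMask")) gt@voxels else gt
  if (length(dim(p)) == 2L) p <- array(p, c(dim(p), 1L))
  if (length(dim(g)) == 2L) g <- array(g, c(dim(g), 1L))
  if (!identical(dim(p), dim(g))) stop("masks must be congruent")
  classify <- function(voxA, voxB) {
    # components of voxA split by whether they touch voxB
    hit <- list(); miss <- list()
    for (co in .allComponents(voxA, connectivity)) {
      touches <- any(voxB[, , co$slice][co$px] > 0)
      row <- data.frame(slice = co$slice, size = nrow(co$px))
      if (touches) hit[[length(hit) + 1L]] <- row
      else miss[[length(miss) + 1L]] <- row
    }
    list(hit = if (length(hit)) do.call(rbind, hit) else
           data.frame(slice = integer(0), size = integer(0)),
         miss = if (length(miss)) do.call(rbind, miss) else
           data.frame(slice = integer(0), size = integer(0)))
  }
  predSplit <- classify(p, g)
  gtSplit <- classify(g, p)
  list(tp = predSplit$hit, fp = predSplit$miss, fn = gtSplit$miss)
}

#' Evaluate one subject
#'
#' @param pred,gt predicted and reference [LesionMask-class] (or binary
#'   arrays).
#' @param subjectID identifier recorded in the row.
#' @param connectivity 4 or 8.
#' @return list with `row` (one-row data.frame: subject, dice, n_fp,
#'   n_fn, has_tp, mean_gt_size, dice_defined) and the pooled `fp_sizes`
#'   / `fn_sizes` vectors.
#' @export
evaluateSubject <- function(pred, gt, subjectID = "subject",
                            connectivity = 8L) {
  d <- diceCoefficient(pred, gt)
  cc <- componentConfusion(pred, gt, connectivity)
  g <- if (is(gt, "LesionMask")) gt@voxels else gt
  if (length(dim(g)) == 2L) g <- array(g, c(dim(g), 1L))
  gtSizes <- integer(0)
  for (co in .allComponents(g, connectivity))
    gtSizes <- c(gtSizes, nrow(co$px))
  row <- data.frame(subject = subjectID,
                    dice = d,
                    n_fp = nrow(cc$fp), n_fn = nrow(cc$fn),
                    has_tp = nrow(cc$tp) > 0L,
                    mean_gt_size = if (length(gtSizes)) mean(gtSizes) else NA_real_,
                    dice_defined = !is.nan(d),
                    stringsAsFactors = FALSE)
  list(row = row, fp_sizes = as.integer(cc$fp$size),
       fn_sizes = as.integer(cc$fn$size))
}

#' Aggregate subject evaluations into a cohort report
#'
#' Mean component counts (m#FP, m#FN) are arithmetic means over
#' subjects; mean component sizes (mSFP, mSFN) pool all such components
#' across subjects (subjects with none contribute nothing to the size
#' mean, which is `NaN`-flagged when no component exists anywhere). The
#' detection rate DR is the fraction of subjects with at least one
#' true-positive component.
#'
#' @param evals list of results from [evaluateSubject()].
#' @return an [EvalReport-class].
#' @export
cohortReport <- function(evals) {
  if (length(evals) == 0L) stop("at least one subject is required")
  subjects <- do.call(rbind, lapply(evals, `[[`, "row"))
  fpSizes <- unlist(lapply(evals, `[[`, "fp_sizes"))
  fnSizes <- unlist(lapply(evals, `[[`, "fn_sizes"))
  summary <- data.frame(
    n_subjects = nrow(subjects),
    mean_dice = mean(subjects$dice[subjects$dice_defined]),
    m_fp = mean(subjects$n_fp),
    m_fn = mean(subjects$n_fn),
    ms_fp = if (length(fpSizes)) mean(fpSizes) else NaN,
    ms_fn = if (length(fnSizes)) mean(fnSizes) else NaN,
    dr = mean(subjects$has_tp))
  new("EvalReport", subjects = subjects, summary = summary,
      fpSizes = as.integer(fpSizes), fnSizes = as.integer(fnSizes))
}

#' Stratify a cohort by mean lesion size
#'
#' Subjects whose mean ground-truth lesion size is strictly below the
#' threshold (default 37 px) form the "small" stratum; the rest the
#' "large" stratum. Subjects without any ground-truth lesion are
#' excluded with a warning. An empty stratum yields `NULL`.
#'
#' @param evals list of results from [evaluateSubject()].
#' @param threshold size boundary in pixels (default 37).
#' @return list with `small` and `large` [EvalReport-class] (or `NULL`).
#' @export
stratifyReport <- function(evals, threshold = 37) {
  means <- vapply(evals, function(e) e$row$mean_gt_size, numeric(1))
  noGt <- is.na(means)
  if (any(noGt))
    warning(sum(noGt), " subject(s) without ground-truth lesions excluded",
            " from stratification")
  evals <- evals[!noGt]; means <- means[!noGt]
  small <- evals[means < threshold]
  large <- evals[means >= threshold]
  list(small = if (length(small)) cohortReport(small) else NULL,
       large = if (length(large)) cohortReport(large) else NULL)
}
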