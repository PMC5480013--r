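makeSliceFixture <- function(seed = 1) {
  set.seed(seed)
  slice <- matrix(rnorm(64 * 64), 64, 64)
  mask <- matrix(0, 64, 64)
  mask[20:23, 30:34] <- 1    # 20 lesion pixels
  list(slice = slice, mask = mask)
}

test_that("one patch is extracted per lesion pixel", {
  fx <- makeSliceFixture()
  ps <- extractLesionPatches(fx$slice, fx$mask, 16L, seed = 3L)
  expect_equal(nPatches(ps), 20L)
  expect_equal(nPatches(extractLesionPatches(fx$slice, matrix(0, 64, 64),
                                             16L)), 0L)
})

test_that("every patch carries its anchor lesion pixel at the recorded offset", {
  fx <- makeSliceFixture()
  ps <- extractLesionPatches(fx$slice, fx$mask, 16L, seed = 3L)
  for (i in seq_len(nPatches(ps))) {
    off <- c(ps@meta$offset_r[i], ps@meta$offset_c[i])
    expect_equal(ps@labels[off[1] + 1L, off[2] + 1L, i], 1)
    expect_equal(ps@images[off[1] + 1L, off[2] + 1L, i],
                 fx$slice[ps@meta$anchor_r[i], ps@meta$anchor_c[i]])
  }
})

test_that("out-of-window regions are zero-padded and extraction is deterministic", {
  slice <- matrix(1, 16, 16)
  mask <- matrix(0, 16, 16); mask[1, 1] <- 1   # corner anchor
  ps <- extractLesionPatches(slice, mask, 16L, seed = 2L)
  img <- ps@images[, , 1]
  expect_true(any(img == 0))                   # padding present
  expect_true(all(img %in% c(0, 1)))
  ps2 <- extractLesionPatches(slice, mask, 16L, seed = 2L)
  expect_identical(ps@images, ps2@images)
  expect_identical(ps@meta, ps2@meta)
  expect_error(extractLesionPatches(slice, mask, 6L), ">= 8")
  expect_error(extractLesionPatches(slice, mask, 64L), "twice")
})

test_that("forced horizontal flip is an involution", {
  fx <- makeSliceFixture()
  ps <- extractLesionPatches(fx$slice, fx$mask, 16L, seed = 1L)
  f1 <- augmentPatches(ps, flip = TRUE, rotation = 0)
  f2 <- augmentPatches(f1, flip = TRUE, rotation = 0)
  expect_equal(f2@images, ps@images)
  expect_equal(f2@labels, ps@labels)
})

test_that("right-angle rotation moves a single label pixel to the mapped coordinate", {
  img <- matrix(0, 8, 8); lab <- matrix(0, 8, 8)
  lab[2, 5] <- 1; img[2, 5] <- 9
  ps <- new("PatchSet", images = array(img, c(8, 8, 1)),
            labels = array(lab, c(8, 8, 1)),
            meta = data.frame(subject = "s", slice = 1L, anchor_r = 2L,
                              anchor_c = 5L, offset_r = 1L, offset_c = 4L,
                              aug = "", stringsAsFactors = FALSE))
  r <- augmentPatches(ps, flip = FALSE, rotation = 90)
  # 90 deg counter-clockwise: (r, c) -> (n + 1 - c, r)
  expect_equal(which(r@labels[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 8 + 1 - 5, col = 2))
  expect_equal(r@images[4, 2, 1], 9)
})

test_that("augmentation preserves the lesion pixel count", {
  fx <- makeSliceFixture()
  ps <- extractLesionPatches(fx$slice, fx$mask, 16L, seed = 5L)
  a <- augmentPatches(ps, seed = 9L)
  for (i in seq_len(nPatches(ps)))
    expect_equal(sum(a@labels[, , i]), sum(ps@labels[, , i]))
  expect_true(all(a@labels %in% c(0, 1)))
})

test_that("subject split follows the floor rule with no leakage", {
  cfg <- phantomConfig(imageSize = 64L, nSlices = 2L,
                       lesionCountRange = c(1L, 2L), seed = 21L)
  cohort <- generateCohort(cfg, 10L)$subjects
  sets <- buildTrainingSet(cohort, patchSize = 16L, seed = 4L,
                           valFraction = 0.3)
  expect_equal(sum(sets$split$set == "train"), 7L)
  expect_equal(sum(sets$split$set == "val"), 3L)
  trainSubs <- unique(sets$train@meta$subject)
  valSubs <- unique(sets$val@meta$subject)
  expect_length(intersect(trainSubs, valSubs), 0L)
  expect_true(all(valSubs %in% sets$split$subject[sets$split$set == "val"]))
  sets2 <- buildTrainingSet(cohort, patchSize = 16L, seed = 4L,
                            valFraction = 0.3)
  expect_identical(sets$train@images, sets2$train@images)
  expect_identical(sets$split, sets2$split)
  expect_error(buildTrainingSet(cohort[1], patchSize = 16L,
                                valFraction = 0.5), "split")
})

test_that("lesion-anchored patches rebalance the label distribution", {
  cfg <- phantomConfig(imageSize = 96L, nSlices = 2L,
                       lesionCountRange = c(1L, 3L), seed = 31L)
  cohort <- generateCohort(cfg, 5L)$subjects
  patchFrac <- c(); sliceFrac <- c()
  for (s in cohort) {
    m <- voxels(s@lesionMask)
    for (k in seq_len(dim(m)[3])) {
      if (sum(m[, , k]) == 0) next
      ps <- extractLesionPatches(voxels(s@volume)[, , k], m[, , k], 64L,
                                 seed = 7L)
      patchFrac <- c(patchFrac, mean(ps@labels))
      sliceFrac <- c(sliceFrac, mean(m[, , k]))
    }
  }
  expect_gt(mean(patchFrac), mean(sliceFrac))
})
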