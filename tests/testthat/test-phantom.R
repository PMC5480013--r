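test_that("empty object ranges yield empty masks", {
  cfg <- phantomConfig(imageSize = 64L, nSlices = 2L,
                       lesionCountRange = c(0L, 0L),
                       artefactCountRange = c(0L, 0L), seed = 1L)
  s <- generateSubject(cfg, 1L)
  expect_equal(sum(voxels(s@lesionMask)), 0)
  expect_equal(sum(voxels(s@artefactMask)), 0)
})

test_that("generation is bit-identical for a fixed seed pair", {
  cfg <- phantomConfig(imageSize = 64L, nSlices = 2L, seed = 9L)
  s1 <- generateSubject(cfg, 3L)
  s2 <- generateSubject(cfg, 3L)
  expect_identical(voxels(s1@volume), voxels(s2@volume))
  expect_identical(voxels(s1@lesionMask), voxels(s2@lesionMask))
  s3 <- generateSubject(cfg, 4L)
  expect_false(identical(voxels(s3@volume), voxels(s1@volume)))
})

test_that("fractionSmall = 1 keeps every lesion component below 37 px", {
  cfg <- phantomConfig(imageSize = 96L, nSlices = 3L, fractionSmall = 1,
                       lesionCountRange = c(5L, 5L), seed = 2L)
  for (k in 1:3) {
    st <- lesionSizeStats(generateSubject(cfg, k)@lesionMask)
    expect_true(all(st$sizes < 37))
  }
})

test_that("lesion and artefact components never overlap and lesions are bright", {
  cfg <- phantomConfig(imageSize = 96L, nSlices = 3L,
                       lesionCountRange = c(2L, 4L),
                       artefactCountRange = c(2L, 4L), seed = 5L)
  for (k in 1:3) {
    s <- generateSubject(cfg, k)
    lm <- voxels(s@lesionMask); am <- voxels(s@artefactMask)
    expect_equal(sum(lm * am), 0)
    if (sum(lm) == 0) next
    v <- voxels(s@volume)
    tissue <- v > 0.5 & lm == 0 & am == 0
    expect_gte(mean(v[lm == 1]) - mean(v[tissue]),
               0.5 * cfg@lesionContrast)
  }
})

test_that("artefact components sit near the brain boundary", {
  cfg <- phantomConfig(imageSize = 96L, nSlices = 2L,
                       lesionCountRange = c(0L, 0L),
                       artefactCountRange = c(4L, 6L), seed = 6L)
  s <- generateSubject(cfg, 1L)
  am <- voxels(s@artefactMask)
  expect_gt(sum(am), 0)
  v <- voxels(s@volume)
  # every artefact pixel lies in the brain, and each component's centroid
  # is closer to the boundary (dark exterior nearby) than to the centre
  px <- which(am == 1, arr.ind = TRUE)
  ctr <- dim(am)[1:2] / 2
  d <- sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
  expect_true(all(d > 0.55 * min(ctr)))
})

test_that("cohort manifests are deterministic and classed by the 37 px rule", {
  cfg <- phantomConfig(imageSize = 64L, nSlices = 2L, seed = 3L)
  c1 <- generateCohort(cfg, 3L)
  c2 <- generateCohort(cfg, 3L)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 3L)
  for (i in seq_len(3)) {
    st <- lesionSizeStats(c1$subjects[[i]]@lesionMask)
    expect_equal(c1$manifest$mean_size[i], st$meanSize)
    if (st$defined)
      expect_equal(c1$manifest$class[i],
                   if (st$meanSize < 37) "small" else "large")
  }
  expect_error(generateCohort(cfg, 0L), ">= 1")
})

test_that("the small-lesion fraction is honoured on average", {
  cfg <- phantomConfig(imageSize = 96L, nSlices = 2L, fractionSmall = 0.5,
                       lesionCountRange = c(3L, 5L), seed = 12L)
  sizes <- integer(0)
  k <- 0L
  while (length(sizes) < 100L) {
    k <- k + 1L
    sizes <- c(sizes, lesionSizeStats(generateSubject(cfg, k)@lesionMask)$sizes)
  }
  frac <- mean(sizes[1:100] < 37)
  expect_lt(abs(frac - 0.5), 0.15)
})

test_that("lesion size statistics match hand arithmetic", {
  a <- array(0, c(12, 12, 1))
  a[2:3, 2:6, 1] <- 1           # 10 px
  a[8:11, 6:10, 1] <- 1         # 20 px
  st <- lesionSizeStats(LesionMask(a))
  expect_setequal(st$sizes, c(10L, 20L))
  expect_equal(st$meanSize, 15)
  expect_equal(st$class, "small")
  empty <- lesionSizeStats(LesionMask(array(0, c(6, 6, 1))))
  expect_false(empty$defined)
  expect_length(empty$sizes, 0L)
  expect_true(is.na(empty$meanSize))
  one <- array(0, c(14, 14, 1))
  one[2:12, 3:5, 1] <- 1; one[2:5, 6, 1] <- 1   # 33 + 4 = 37 px, connected
  st37 <- lesionSizeStats(LesionMask(one))
  expect_equal(st37$sizes, 37L)
  expect_equal(st37$meanSize, 37)
  expect_equal(st37$class, "large")
})

test_that("cohort files round-trip through the on-disk layout", {
  cfg <- phantomConfig(imageSize = 48L, nSlices = 2L, seed = 8L)
  co <- generateCohort(cfg, 2L)
  d <- file.path(tempdir(), "phantom-cohort")
  writeCohort(co, d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  v <- readVolume(file.path(d, paste0(man$subject_id[1], "_dwi.nii.gz")),
                  "image")
  expect_equal(dim(voxels(v)), c(48L, 48L, 2L))
  unlink(d, recursive = TRUE)
})
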