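probMapFrom <- function(lesion) {
  d <- dim(lesion)
  p <- array(0, c(d[1], d[2], 2, if (length(d) > 2) d[3] else 1))
  p[, , 2, ] <- lesion
  p[, , 1, ] <- 1 - lesion
  new("ProbabilityMap", probs = p)
}

test_that("binarisation applies the >= threshold rule", {
  l <- array(0, c(2, 2, 1))
  l[1, 1, 1] <- 0.4; l[1, 2, 1] <- 0.5; l[2, 1, 1] <- 0.6
  m <- binarize(probMapFrom(l), 0.5)
  expect_equal(as.vector(voxels(m)), c(0, 1, 1, 0))
  expect_equal(sum(voxels(binarize(probMapFrom(array(0, c(4, 4, 1)))))), 0)
  hi <- probMapFrom(array(0.9, c(4, 4, 1)))
  expect_equal(sum(voxels(binarize(hi, 0.999))), 0)
  expect_error(binarize(hi, 1.2), "threshold")
  expect_error(binarize(hi, 0), "threshold")
})

test_that("candidates split into small and large at the size limit", {
  a <- array(0, c(20, 20, 1))
  a[2:4, 2, 1] <- 1                       # 3 px
  a[8:17, 5:11, 1] <- 1                   # 70 px
  mask <- LesionMask(a)
  p <- probMapFrom(a * 0.9)
  r <- findCandidates(mask, p, limit = 60L)
  expect_length(r$small, 1L)
  expect_length(r$large, 1L)
  expect_equal(r$small[[1]]@size, 3L)
  expect_equal(r$large[[1]]@size, 70L)
  expect_equal(r$small[[1]]@meanProb, 0.9)
  empty <- findCandidates(LesionMask(array(0, c(8, 8, 1))),
                          probMapFrom(array(0, c(8, 8, 1))))
  expect_length(empty$small, 0L)
  expect_length(empty$large, 0L)
})

test_that("diagonal pixels form one component under 8-connectivity", {
  a <- array(0, c(6, 6, 1)); a[2, 2, 1] <- 1; a[3, 3, 1] <- 1
  r8 <- findCandidates(LesionMask(a), probMapFrom(a), connectivity = 8L)
  expect_length(c(r8$small, r8$large), 1L)
  r4 <- findCandidates(LesionMask(a), probMapFrom(a), connectivity = 4L)
  expect_length(c(r4$small, r4$large), 2L)
})

test_that("multi-scale stacks use s = max(bbox side, 8) and zero padding", {
  a <- array(0, c(32, 32, 1)); a[3, 3, 1] <- 1   # 1 px at the corner
  p <- probMapFrom(a)
  cand <- findCandidates(LesionMask(a), p)$small[[1]]
  slice <- matrix(1, 32, 32)
  st <- extractStack(slice, p, cand)
  expect_equal(dim(st), c(16L, 16L, 4L))
  # 4s = 32 px window centred at (3, 3) overhangs the slice -> padding
  expect_true(any(st[, , 3] == 0))
  expect_true(all(is.finite(st)))
  # an interior candidate on a constant slice has constant image channels
  b <- array(0, c(64, 64, 1)); b[30, 30, 1] <- 1
  p2 <- probMapFrom(b)
  cand2 <- findCandidates(LesionMask(b), p2)$small[[1]]
  st2 <- extractStack(matrix(2, 64, 64), p2, cand2)
  for (ch in 1:3) expect_lt(diff(range(st2[, , ch])), 1e-9)
})

test_that("the classifier has 4 convolutions, 1 pooling and 3 FC layers", {
  m <- buildMuscleNet()
  types <- vapply(m@params, `[[`, character(1), "type")
  expect_equal(sum(types == "conv"), 4L)
  expect_equal(sum(types == "pool"), 1L)
  expect_equal(sum(types == "fc"), 3L)
  x <- array(rnorm(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  out <- dwiseg:::.muscleForward(m, x, FALSE)$out
  expect_equal(dim(out), c(3L, 2L))
  expect_equal(rowSums(out), rep(1, 3), tolerance = 1e-9)
})

test_that("candidate labels follow the one-pixel overlap rule", {
  gtA <- array(0, c(16, 16, 1)); gtA[4:8, 4:8, 1] <- 1
  gt <- LesionMask(gtA)
  inside <- array(0, c(16, 16, 1)); inside[5:6, 5:6, 1] <- 1
  disjoint <- array(0, c(16, 16, 1)); disjoint[12:13, 12:13, 1] <- 1
  touch <- array(0, c(16, 16, 1)); touch[8:12, 8, 1] <- 1  # 1 of 5 px in gt
  cands <- lapply(list(inside, disjoint, touch), function(a)
    findCandidates(LesionMask(a), probMapFrom(a))$small[[1]])
  expect_equal(labelCandidates(cands, gt), c(1L, 0L, 1L))
})

test_that("Bayes fusion has the neutral, removing and worked-value behaviour", {
  set.seed(3)
  l <- array(runif(8 * 8, 0.6, 0.95), c(8, 8, 1))
  p <- probMapFrom(l)
  cand <- findCandidates(binarize(p, 0.5), p)$large[[1]]
  same <- bayesFuse(p, cand, 0.5)
  expect_lt(max(abs(probs(same) - probs(p))), 1e-9)
  gone <- bayesFuse(p, cand, 1e-9)
  expect_lt(max(probs(gone)[, , 2, ]), 1e-3)
  l2 <- array(0, c(2, 2, 1)); l2[1, 1, 1] <- 0.8
  p2 <- probMapFrom(l2)
  cand2 <- findCandidates(binarize(p2, 0.5), p2)$small[[1]]
  fused <- bayesFuse(p2, cand2, 0.6)
  expect_equal(probs(fused)[1, 1, 2, 1], 6 / 7, tolerance = 1e-9)
  expect_equal(probs(fused)[1, 1, 1, 1], 1 - 6 / 7, tolerance = 1e-9)
  # untouched pixels stay put
  expect_equal(probs(fused)[2, 2, , 1], probs(p2)[2, 2, , 1])
  expect_error(bayesFuse(p2, cand2, 1.4), "probability")
})

test_that("classifier training learns a separable candidate fixture", {
  set.seed(11)
  n <- 60L
  stacks <- array(rnorm(16 * 16 * 4 * n, 0, 0.2), c(16, 16, 4, n))
  labels <- rep(0:1, each = n / 2)
  # lesions carry bright context in every scale channel; decoys do not
  for (i in which(labels == 1)) stacks[6:10, 6:10, 1:3, i] <-
    stacks[6:10, 6:10, 1:3, i] + 2
  m <- trainMuscle(stacks, labels,
                   trainCfg = trainConfig(maxEpochs = 8L, batchSize = 16L,
                                          seed = 2L))
  expect_true(m@trained)
  expect_lt(m@log$train_loss[nrow(m@log)], m@log$train_loss[1])
  expect_gt(max(m@log$val_acc), 0.8)
  q <- muscleClassify(m, stacks[, , , c(1, n)])
  expect_length(q, 2L)
  expect_true(all(q >= 0 & q <= 1))
  m2 <- trainMuscle(stacks, labels,
                    trainCfg = trainConfig(maxEpochs = 8L, batchSize = 16L,
                                           seed = 2L))
  expect_identical(m@log, m2@log)
  expect_error(trainMuscle(stacks, rep(1L, n)), "both")
})

test_that("refinement removes rejected small components and keeps large ones", {
  set.seed(5)
  a <- array(0, c(40, 40, 1))
  a[3:5, 3:5, 1] <- 1                    # small component (9 px)
  a[20:32, 15:27, 1] <- 1                # large component (169 px)
  p <- probMapFrom(a * 0.9)
  vol <- DWIVolume(array(rnorm(40 * 40, 0, 0.1), c(40, 40, 1)))
  # classifier biased to reject: train on a fixture where everything that
  # looks like the small component is negative
  rejectAll <- buildMuscleNet(seed = 1L)
  rejectAll@trained <- TRUE
  types <- vapply(rejectAll@params, `[[`, character(1), "type")
  lastFC <- max(which(types == "fc"))
  rejectAll@params[[lastFC]]$W[] <- 0
  rejectAll@params[[lastFC]]$b <- c(20, -20)   # always q ~ 0
  out <- refineSegmentation(p, rejectAll, vol)
  expect_equal(sum(voxels(out$mask)[3:5, 3:5, 1]), 0)          # removed
  expect_equal(sum(voxels(out$mask)[20:32, 15:27, 1]), 169)    # bypassed
  expect_true(all(voxels(out$mask) <= voxels(binarize(p))))    # monotone
  expect_equal(nrow(out$candidates), 2L)
  expect_true(out$candidates$kept[out$candidates$size == 169])
  expect_false(out$candidates$kept[out$candidates$size == 9])
  # with no small candidates the mask equals the plain binarisation
  b <- array(0, c(40, 40, 1)); b[10:22, 10:22, 1] <- 1
  p2 <- probMapFrom(b * 0.9)
  out2 <- refineSegmentation(p2, rejectAll, vol)
  expect_equal(voxels(out2$mask), voxels(binarize(p2)))
})
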