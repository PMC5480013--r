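test_that("Dice matches hand-computed overlaps and is symmetric", {
  x <- array(0, c(8, 8, 1)); y <- array(0, c(8, 8, 1))
  x[1, 1:4, 1] <- 1                   # |X| = 4
  y[1, 2:7, 1] <- 1                   # |Y| = 6, intersection = 3
  expect_equal(diceCoefficient(x, y), 2 * 3 / 10)
  expect_equal(diceCoefficient(y, x), diceCoefficient(x, y))
  expect_equal(diceCoefficient(x, x), 1)
  z <- array(0, c(8, 8, 1)); z[5, 5, 1] <- 1
  expect_equal(diceCoefficient(x, z), 0)
  expect_true(is.nan(diceCoefficient(z * 0, z * 0)))
  expect_error(diceCoefficient(x, array(0, c(4, 4, 1))), "congruent")
})

test_that("component confusion matches the toy example", {
  pred <- array(0, c(16, 16, 1)); gt <- array(0, c(16, 16, 1))
  gt[2:3, 2:4, 1] <- 1                    # gt lesion A (6 px)
  gt[12:14, 9:10, 1] <- 1                 # gt lesion B (6 px), untouched
  pred[2:3, 2:3, 1] <- 1; pred[4, 2, 1] <- 1   # 5 px, overlaps A
  pred[8:9, 14, 1] <- 1; pred[10, 14, 1] <- 1  # 3 px, isolated
  cc <- componentConfusion(pred, gt)
  expect_equal(nrow(cc$tp), 1L)
  expect_equal(cc$tp$size, 5L)
  expect_equal(nrow(cc$fp), 1L)
  expect_equal(cc$fp$size, 3L)
  expect_equal(nrow(cc$fn), 1L)
  expect_equal(cc$fn$size, 6L)
})

test_that("degenerate confusion cases behave", {
  gt <- array(0, c(10, 10, 1)); gt[2:3, 2:3, 1] <- 1; gt[7:8, 7:8, 1] <- 1
  same <- componentConfusion(gt, gt)
  expect_equal(nrow(same$fp), 0L)
  expect_equal(nrow(same$fn), 0L)
  expect_equal(nrow(same$tp), 2L)
  none <- componentConfusion(gt * 0, gt)
  expect_equal(nrow(none$fp), 0L)
  expect_equal(nrow(none$fn), 2L)
})

test_that("confusion counts satisfy the partition identities", {
  set.seed(21)
  for (i in 1:25) {
    pred <- array(randomMask(16, 16, 0.25), c(16, 16, 1))
    gt <- array(randomMask(16, 16, 0.25), c(16, 16, 1))
    cc <- componentConfusion(pred, gt)
    nPred <- length(bfConfusion(pred[, , 1], gt[, , 1])$tp) +
      length(bfConfusion(pred[, , 1], gt[, , 1])$fp)
    expect_equal(nrow(cc$tp) + nrow(cc$fp), nPred)
    expect_lte(nrow(cc$fn), max(bfLabel(gt[, , 1])))
  }
})

test_that("cohort aggregation follows the stated formulas", {
  mk <- function(dice, nfp, nfn, hastp, meansz, fpsz = integer(0),
                 fnsz = integer(0), id = "s") {
    list(row = data.frame(subject = id, dice = dice, n_fp = nfp, n_fn = nfn,
                          has_tp = hastp, mean_gt_size = meansz,
                          dice_defined = !is.nan(dice),
                          stringsAsFactors = FALSE),
         fp_sizes = as.integer(fpsz), fn_sizes = as.integer(fnsz))
  }
  evals <- list(mk(0.8, 2L, 0L, TRUE, 20, fpsz = c(3, 9), id = "a"),
                mk(0.5, 0L, 1L, TRUE, 50, fnsz = 7, id = "b"),
                mk(0.0, 4L, 2L, FALSE, 10, fpsz = c(2, 2, 5, 11),
                   fnsz = c(4, 6), id = "c"))
  rep <- cohortReport(evals)
  expect_equal(rep@summary$dr, 2 / 3)
  expect_equal(rep@summary$m_fp, 2)
  expect_equal(rep@summary$m_fn, 1)
  expect_equal(rep@summary$ms_fp, mean(c(3, 9, 2, 2, 5, 11)))
  expect_equal(rep@summary$ms_fn, mean(c(7, 4, 6)))
  expect_equal(rep@summary$mean_dice, mean(c(0.8, 0.5, 0)))
  noFP <- cohortReport(list(mk(1, 0L, 0L, TRUE, 40)))
  expect_true(is.nan(noFP@summary$ms_fp))
  expect_equal(noFP@summary$m_fp, 0)
  expect_error(cohortReport(list()), "at least one")
})

test_that("stratification splits strictly at the boundary", {
  mk <- function(meansz, id) {
    list(row = data.frame(subject = id, dice = 0.5, n_fp = 0L, n_fn = 0L,
                          has_tp = TRUE, mean_gt_size = meansz,
                          dice_defined = TRUE, stringsAsFactors = FALSE),
         fp_sizes = integer(0), fn_sizes = integer(0))
  }
  evals <- list(mk(10, "a"), mk(36.9, "b"), mk(37, "c"), mk(80, "d"))
  st <- stratifyReport(evals)
  expect_equal(st$small@subjects$subject, c("a", "b"))
  expect_equal(st$large@subjects$subject, c("c", "d"))
  allSmall <- stratifyReport(list(mk(5, "a"), mk(6, "b")))
  expect_null(allSmall$large)
  expect_equal(nrow(allSmall$small@subjects), 2L)
  expect_warning(stratifyReport(c(evals, list(mk(NA_real_, "e")))),
                 "excluded")
  expect_equal(nrow(st$small@subjects) + nrow(st$large@subjects),
               length(evals))
})

test_that("subject evaluation bundles Dice, components and detection", {
  gt <- array(0, c(16, 16, 2)); gt[3:6, 3:6, 1] <- 1
  pred <- gt; pred[12:13, 12:13, 2] <- 1   # one FP component on slice 2
  ev <- evaluateSubject(pred, gt, "s1")
  expect_equal(ev$row$n_fp, 1L)
  expect_equal(ev$row$n_fn, 0L)
  expect_true(ev$row$has_tp)
  expect_equal(ev$row$mean_gt_size, 16)
  expect_equal(ev$fp_sizes, 4L)
  expect_gt(ev$row$dice, 0.8)
})
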