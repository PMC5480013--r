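test_that("max pooling records the argmax location", {
  # window [[1,3],[2,0]] -> pooled 3 at within-window position (0,1)
  m <- matrix(c(1, 2, 3, 0), 2, 2)   # rows: (1,3) / (2,0)
  r <- maxPoolWithMask(m, 2L)
  expect_equal(r$pooled[1, 1, 1, 1], 3)
  expect_equal(r$mask@index[1, 1, 1, 1], 1L)   # row-major index 0*2+1
  u <- unpoolWithMask(r$pooled, r$mask)
  expect_equal(u[, , 1, 1], matrix(c(0, 0, 3, 0), 2, 2))
})

test_that("pooling ties break to the first position in row-major order", {
  m <- matrix(4, 2, 2)
  r <- maxPoolWithMask(m, 2L)
  expect_equal(r$pooled[1, 1, 1, 1], 4)
  expect_equal(r$mask@index[1, 1, 1, 1], 0L)
})

test_that("pooled shape contracts and mismatches error", {
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  r <- maxPoolWithMask(x, 2L)
  expect_equal(dim(r$pooled), c(4L, 4L, 3L, 2L))
  expect_error(maxPoolWithMask(array(rnorm(7 * 8), c(7, 8, 1, 1)), 2L),
               "divisible")
  expect_error(unpoolWithMask(array(0, c(3, 3, 1, 1)), r$mask), "match")
})

test_that("unpooling all zeros stays zero and round trips place maxima", {
  z <- array(0, c(4, 4, 1, 1))
  mk <- maxPoolWithMask(array(rnorm(64), c(8, 8, 1, 1)), 2L)$mask
  expect_true(all(unpool_fwd(z, mk@index, 2L) == 0))
  set.seed(8)
  for (trial in 1:50) {
    m <- matrix(rnorm(36), 6, 6)
    r <- maxPoolWithMask(m, 2L)
    u <- unpoolWithMask(r$pooled, r$mask)[, , 1, 1]
    bf <- bfPool(m, 2L)
    for (pr in 1:3) for (pc in 1:3) {
      idx <- bf$mask[pr, pc]
      wr <- idx %/% 2; wc <- idx %% 2
      expect_equal(u[(pr - 1) * 2 + wr + 1, (pc - 1) * 2 + wc + 1],
                   bf$out[pr, pc])
    }
    expect_equal(sum(u != 0), sum(bf$out != 0))
  }
})

test_that("the branch mirrors its encoder and keeps 3x3 stride-1 filters", {
  cfg <- networkConfig()
  layers <- buildBranch(cfg)
  types <- vapply(layers, `[[`, character(1), "type")
  expect_equal(sum(types == "pool"), 2L)     # three stacks, two poolings
  expect_equal(sum(types == "unpool"), 2L)
  convs <- layers[types == "conv"]
  ks <- vapply(convs, `[[`, integer(1), "k")
  expect_true(all(ks[-length(ks)] == 3L))
  expect_equal(ks[length(ks)], 1L)           # 1x1 head
  # unpooling consumes the masks in reverse order of their recording
  poolIds <- vapply(layers[types == "pool"], `[[`, character(1), "id")
  unpoolIds <- vapply(layers[types == "unpool"], `[[`, character(1), "id")
  expect_equal(unpoolIds, rev(poolIds))
})

test_that("a branch turns a 64x64 patch into a 2-channel probability map", {
  cfg <- tinyNetConfig(64L)
  model <- initEDD(cfg, seed = 2L)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  out <- dwiseg:::.netForward(model@branches[[1]], x, training = FALSE)$out
  expect_equal(dim(out), c(64L, 64L, 2L, 1L))
  expect_lt(max(abs(out[, , 1, ] + out[, , 2, ] - 1)), 1e-5)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("receptive field follows the layer recursion", {
  # conv-only oracle: gradient support of one output pixel
  support <- function(layers, side) {
    for (i in seq_along(layers)) {
      layers[[i]]$W[] <- 1; layers[[i]]$b[] <- 0
    }
    x <- array(0, c(side, side, 1, 1))
    fw <- dwiseg:::.netForward(layers, x, training = FALSE)
    g <- array(0, dim(fw$out))
    ctr <- (side + 1) %/% 2
    g[ctr, ctr, 1, 1] <- 1
    gx <- dwiseg:::.netBackward(layers, fw$caches, g,
                                needInputGrad = TRUE)$gx
    rows <- range(which(apply(gx[, , 1, 1] != 0, 1, any)))
    rows[2] - rows[1] + 1L
  }
  twoConvs <- list(dwiseg:::.layerConv(1L, 1L, 3L),
                   dwiseg:::.layerConv(1L, 1L, 3L))
  expect_equal(support(twoConvs, 15L), 5L)
  expect_equal(support(twoConvs[1], 15L), 3L)
  # the scaled-down operating point: receptive field equals patch size
  expect_equal(receptiveField(tinyNetConfig(32L)), 32L)
  cfg <- networkConfig()
  expect_lte(receptiveField(cfg), cfg@patchSize)
  expect_warning(networkConfig(convStacks = 3L, convsPerStack = 2L,
                               patchSize = 32L), "receptive field")
})

test_that("the ensemble is the pixel-wise mean of branch probabilities", {
  cfg <- tinyNetConfig()
  model <- initEDD(cfg, seed = 5L)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  p1 <- dwiseg:::.netForward(model@branches[[1]], x, FALSE)$out
  p2 <- dwiseg:::.netForward(model@branches[[2]], x, FALSE)$out
  h <- ensembleForward(model, x)
  expect_equal(h, (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(dim(h)[1:2], dim(x)[1:2])
  # mean of equals and the 0.2 / 0.6 arithmetic check
  twin <- model; twin@branches[[2]] <- twin@branches[[1]]
  expect_equal(ensembleForward(twin, x), p1, tolerance = 1e-12)
  expect_equal((0.2 + 0.6) / 2, 0.4)
  mix <- (array(c(0.8, 0.2), c(1, 1, 2, 1)) +
            array(c(0.4, 0.6), c(1, 1, 2, 1))) / 2
  expect_equal(mix[1, 1, 2, 1], 0.4)
})

test_that("branches are initialised differently", {
  model <- initEDD(tinyNetConfig(), seed = 1L)
  expect_false(identical(model@branches[[1]][[1]]$W,
                         model@branches[[2]][[1]]$W))
})

test_that("refinement preserves shape and a pass-through construction reproduces argmax", {
  cfg <- tinyNetConfig()
  model <- initEDD(cfg, seed = 3L)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  set.seed(1)
  hl <- matrix(runif(32 * 32, 0.05, 0.95), 32, 32)
  h <- array(0, c(32, 32, 2, 1))
  h[, , 2, 1] <- hl; h[, , 1, 1] <- 1 - hl
  H <- refineForward(model, h, x)
  expect_equal(dim(H), c(32L, 32L, 2L, 1L))
  expect_lt(max(abs(H[, , 1, ] + H[, , 2, ] - 1)), 1e-5)
  # construct pass-through weights: channel i of every refinement conv
  # carries h's channel i; the 1x1 head amplifies them
  types <- vapply(model@refine, `[[`, character(1), "type")
  convIdx <- which(types == "conv")
  for (j in seq_along(convIdx)) {
    i <- convIdx[j]
    ly <- model@refine[[i]]
    model@refine[[i]]$W[] <- 0
    model@refine[[i]]$b[] <- 0
    if (ly$k == 3L) {
      src <- if (j == 1L) c(2L, 3L) else c(1L, 2L)  # h channels at input
      model@refine[[i]]$W[1, (src[1] - 1L) * 9L + 5L] <- 1
      model@refine[[i]]$W[2, (src[2] - 1L) * 9L + 5L] <- 1
    } else {
      model@refine[[i]]$W[1, 1] <- 50
      model@refine[[i]]$W[2, 2] <- 50
    }
  }
  H2 <- refineForward(model, h, x)
  expect_equal(H2[, , 2, 1] > 0.5, hl > 0.5)
})

test_that("the deeply supervised loss matches its closed forms", {
  p <- 16L
  uni <- array(0.5, c(p, p, 2, 1))
  y <- matrix(rbinom(p * p, 1, 0.4), p, p)
  expect_equal(eddLoss(list(uni, uni), uni, uni, y, lambda = 1), 4 * log(2),
               tolerance = 1e-9)
  onehot <- array(0, c(p, p, 2, 1))
  onehot[, , 2, 1] <- y; onehot[, , 1, 1] <- 1 - y
  expect_lt(eddLoss(list(onehot, onehot), onehot, onehot, y), 1e-5)
  # weight masking: lambda = (1, 0, 0, 0) keeps only the refined term
  set.seed(2)
  r <- array(runif(p * p * 2), c(p, p, 2, 1))
  r <- r / rep(r[, , 1, ] + r[, , 2, ], 2)
  lH <- eddLoss(list(uni, uni), uni, r, y, lambda = c(1, 0, 0, 0))
  expect_equal(lH, eddLoss(list(r, r), r, r, y, lambda = c(1, 0, 0, 0)))
  # additivity: all-ones weights equal the sum of the four terms
  l <- eddLoss(list(uni, r), r, uni, y, lambda = 1)
  parts <- eddLoss(list(uni, uni), uni, uni, y, c(0, 0, 1, 0)) +
    eddLoss(list(r, r), r, r, y, c(0, 0, 0, 1)) +
    eddLoss(list(uni, uni), r, uni, y, c(0, 1, 0, 0)) +
    eddLoss(list(uni, uni), uni, uni, y, c(1, 0, 0, 0))
  expect_equal(l, parts, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- networkConfig(nBranches = 2L, convStacks = 2L, convsPerStack = 1L,
                       baseChannels = 4L, patchSize = 16L,
                       refinementConvs = 2L)
  model <- initEDD(cfg, seed = 3L)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  lossOf <- function(m) {
    fw <- dwiseg:::.eddForward(m, x, training = TRUE)
    eddLoss(fw$branchOut, fw$h, fw$H, y, lambda = 1)
  }
  fw <- dwiseg:::.eddForward(model, x, training = TRUE)
  dH <- dwiseg:::.ceProbGrad(fw$H, y, 1)
  rb <- dwiseg:::.netBackward(model@refine, fw$rres$caches, dH,
                              needInputGrad = TRUE)
  dh <- dwiseg:::.ceProbGrad(fw$h, y, 1) + rb$gx[, , 2:3, , drop = FALSE]
  dp <- dwiseg:::.ceProbGrad(fw$branchOut[[1]], y, 1) + dh / 2
  bb <- dwiseg:::.netBackward(model@branches[[1]], fw$bres[[1]]$caches, dp)
  l0 <- lossOf(model); eps <- 1e-6
  m2 <- model
  m2@branches[[1]][[1]]$W[2, 3] <- m2@branches[[1]][[1]]$W[2, 3] + eps
  expect_equal((lossOf(m2) - l0) / eps, bb$grads[[1]]$W[2, 3],
               tolerance = 1e-3)
  m3 <- model
  m3@branches[[1]][[2]]$gamma[2] <- m3@branches[[1]][[2]]$gamma[2] + eps
  expect_equal((lossOf(m3) - l0) / eps, bb$grads[[2]]$gamma[2],
               tolerance = 1e-3)
  m4 <- model
  m4@refine[[1]]$W[1, 4] <- m4@refine[[1]]$W[1, 4] + eps
  expect_equal((lossOf(m4) - l0) / eps, rb$grads[[1]]$W[1, 4],
               tolerance = 1e-3)
})
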