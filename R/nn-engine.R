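# Minimal feed-forward network engine on (H, W, C, N) arrays.
#
# A network is a plain list of layer lists. Convolution and pooling run
# through the compiled kernels; batch normalisation, ReLU, softmax and the
# fully connected layers are vectorised R. Backpropagation is explicit:
# .netForward returns per-layer caches, .netBackward walks them in
# reverse. Layers are value objects; training-mode forward passes return
# updated layers so that batch-norm running statistics persist.

.xavier <- function(fanIn, fanOut, nr, nc) {
  a <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -a, a), nr, nc)
}

.layerConv <- function(cin, cout, k = 3L) {
  list(type = "conv", k = as.integer(k), pad = as.integer((k - 1) / 2),
       cin = cin, cout = cout,
       W = .xavier(cin * k * k, cout * k * k, cout, cin * k * k),
       b = numeric(cout))
}

.layerBN <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), bnMomentum = 0.1)
}

.layerReLU <- function() list(type = "relu")
.layerPool <- function(window, id) list(type = "pool", window = as.integer(window), id = id)
.layerUnpool <- function(window, id) list(type = "unpool", window = as.integer(window), id = id)
.layerSoftmax <- function() list(type = "softmax")
.layerFlatten <- function() list(type = "flatten")
.layerFC <- function(nin, nout) {
  list(type = "fc", nin = nin, nout = nout,
       W = .xavier(nin, nout, nout, nin), b = numeric(nout))
}
.layerReLUv <- function() list(type = "reluv")
.layerSoftmaxv <- function() list(type = "softmaxv")

.softmax4 <- function(z) {
  d <- dim(z); C <- d[3]
  m <- z[, , 1, , drop = FALSE]
  if (C > 1) for (ch in 2:C) m <- pmax(m, z[, , ch, , drop = FALSE])
  p <- z
  s <- array(0, d[c(1, 2, 4)])
  for (ch in seq_len(C)) {
    p[, , ch, ] <- exp(z[, , ch, ] - m[, , 1, ])
    s <- s + p[, , ch, ]
  }
  for (ch in seq_len(C)) p[, , ch, ] <- p[, , ch, ] / s
  p
}

# dz from gradient w.r.t. softmax output probabilities (general form:
# probabilities may receive gradient from several consumers).
.softmax4Bwd <- function(p, dp) {
  d <- dim(p); C <- d[3]
  s <- array(0, d[c(1, 2, 4)])
  for (ch in seq_len(C)) s <- s + dp[, , ch, ] * p[, , ch, ]
  dz <- p
  for (ch in seq_len(C)) dz[, , ch, ] <- p[, , ch, ] * (dp[, , ch, ] - s)
  dz
}

.netForward <- function(layers, x, training = TRUE, masks = list()) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      caches[[i]] <- list(x = x)
      x <- conv2d_fwd(x, ly$W, ly$b, ly$k, ly$pad)
    } else if (ly$type == "bn") {
      d <- dim(x)
      useBatch <- training && prod(d[c(1, 2, 4)]) > 1
      r <- bn_fwd(x, ly$gamma, ly$beta, ly$rmean, ly$rvar, useBatch)
      if (useBatch) {
        layers[[i]]$rmean <- (1 - ly$bnMomentum) * ly$rmean + ly$bnMomentum * r$mean
        layers[[i]]$rvar <- (1 - ly$bnMomentum) * ly$rvar + ly$bnMomentum * r$var
      }
      caches[[i]] <- list(x = x, mu = r$mean, va = r$var, train = useBatch)
      x <- r$y
    } else if (ly$type == "relu") {
      x <- relu_fwd(x)
      caches[[i]] <- list(y = x)
    } else if (ly$type == "pool") {
      pm <- maxpool_fwd(x, ly$window)
      masks[[ly$id]] <- pm$mask
      caches[[i]] <- list(mask = pm$mask)
      x <- pm$out
    } else if (ly$type == "unpool") {
      mk <- masks[[ly$id]]
      if (is.null(mk)) stop("no pooling mask recorded for id ", ly$id)
      caches[[i]] <- list(mask = mk)
      x <- unpool_fwd(x, mk, ly$window)
    } else if (ly$type == "softmax") {
      x <- if (dim(x)[3] == 2L) softmax2_fwd(x) else .softmax4(x)
      caches[[i]] <- list(p = x)
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(d = d)
      x <- t(matrix(x, prod(d[1:3]), d[4]))
    } else if (ly$type == "fc") {
      caches[[i]] <- list(x = x)
      x <- x %*% t(ly$W) + rep(ly$b, each = nrow(x))
    } else if (ly$type == "reluv") {
      caches[[i]] <- list(pos = x > 0)
      x <- x * (x > 0)
    } else if (ly$type == "softmaxv") {
      m <- apply(x, 1, max)
      e <- exp(x - m)
      x <- e / rowSums(e)
      caches[[i]] <- list(p = x)
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches, masks = masks, layers = layers)
}

.netBackward <- function(layers, caches, g, needInputGrad = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    if (ly$type == "conv") {
      r <- conv2d_bwd(ca$x, ly$W, g, ly$k, ly$pad)
      grads[[i]] <- list(W = r$gW, b = r$gb)
      if (i > 1L || needInputGrad) g <- r$gx else g <- NULL
    } else if (ly$type == "bn") {
      r <- bn_bwd(ca$x, g, ly$gamma, ca$mu, ca$va, ca$train)
      grads[[i]] <- list(gamma = r$ggamma, beta = r$gbeta)
      g <- r$gx
    } else if (ly$type == "relu") {
      g <- relu_bwd(g, ca$y)
    } else if (ly$type == "reluv") {
      g <- g * ca$pos
    } else if (ly$type == "pool") {
      g <- unpool_fwd(g, ca$mask, ly$window)
    } else if (ly$type == "unpool") {
      g <- mask_gather(g, ca$mask, ly$window)
    } else if (ly$type == "softmax") {
      g <- if (dim(ca$p)[3] == 2L) softmax2_bwd(ca$p, g) else .softmax4Bwd(ca$p, g)
    } else if (ly$type == "softmaxv") {
      s <- rowSums(g * ca$p)
      g <- ca$p * (g - s)
    } else if (ly$type == "flatten") {
      g <- array(t(g), ca$d)
    } else if (ly$type == "fc") {
      grads[[i]] <- list(W = t(g) %*% ca$x, b = colSums(g))
      g <- g %*% ly$W
    }
  }
  list(grads = grads, gx = g)
}

# Per-pixel cross-entropy of a 2-class probability map against a binary
# label array (H, W, N), averaged over pixels and batch. Probabilities are
# clipped to \[1e-7, 1 - 1e-7\].
.ceProb <- function(p, y) {
  if (is.matrix(y)) y <- array(y, c(dim(y), 1L))
  storage.mode(y) <- "double"
  ce_prob(p, y)
}

# Gradient of lambda * .ceProb with respect to the probability map.
.ceProbGrad <- function(p, y, lambda = 1) {
  if (is.matrix(y)) y <- array(y, c(dim(y), 1L))
  storage.mode(y) <- "double"
  ce_prob_grad(p, y, lambda)
}

# Cross-entropy for instance classification: probs (N x 2), labels 0/1.
.ceInstance <- function(p, y) {
  pt <- ifelse(y > 0.5, p[, 2], p[, 1])
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  -mean(log(pt))
}

.ceInstanceGrad <- function(p, y) {
  g <- matrix(0, nrow(p), 2)
  M <- nrow(p)
  pt <- pmin(pmax(ifelse(y > 0.5, p[, 2], p[, 1]), 1e-7), 1 - 1e-7)
  g[cbind(seq_len(M), ifelse(y > 0.5, 2L, 1L))] <- -1 / (M * pt)
  g
}

# SGD with momentum (and optional weight decay) over a list of layer
# lists. Velocities are kept in a parallel structure.
.sgdInitVelocity <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "fc"))
      list(W = ly$W * 0, b = ly$b * 0)
    else if (ly$type == "bn")
      list(gamma = ly$gamma * 0, beta = ly$beta * 0)
    else NULL
  })
}

.sgdStep <- function(layers, grads, vel, lr, momentum, weightDecay) {
  for (i in seq_along(layers)) {
    gr <- grads[[i]]
    if (is.null(gr)) next
    for (nm in names(gr)) {
      g <- gr[[nm]]
      if (weightDecay > 0 && nm %in% c("W"))
        g <- g + weightDecay * layers[[i]][[nm]]
      vel[[i]][[nm]] <- momentum * vel[[i]][[nm]] - lr * g
      layers[[i]][[nm]] <- layers[[i]][[nm]] + vel[[i]][[nm]]
    }
  }
  list(layers = layers, vel = vel)
}

# Accumulate two grad structures (same shape).
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}
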