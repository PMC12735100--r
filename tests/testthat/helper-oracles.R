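# Independent oracles used by the tests: straight-line re-implementations
# on plain nested loops (convolution, batch norm, the full main block),
# label-counting metrics, and pair-counting AUC. They share nothing with
# the package's kernels beyond the documented conventions.

naiveConv <- function(x, w, stride, groups) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  k <- dim(w)[1]; cing <- dim(w)[3]; cout <- dim(w)[4]
  coutg <- cout / groups
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  pt <- max(0, (Ho - 1) * stride + k - H) %/% 2
  pl <- max(0, (Wo - 1) * stride + k - W) %/% 2
  out <- array(0, c(Ho, Wo, cout))
  for (oc in seq_len(cout)) {
    g <- (oc - 1) %/% coutg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cing)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        hi <- (ho - 1) * stride - pt + (kh - 1)
        wi <- (wo - 1) * stride - pl + (kw - 1)
        if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
          acc <- acc + x[hi + 1, wi + 1, g * cing + ci] * w[kh, kw, ci, oc]
        }
      }
      out[ho, wo, oc] <- acc
    }
  }
  out
}

naiveBn <- function(x, bn) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- bn$gamma[c] * (x[, , c] - bn$rmean[c]) /
      sqrt(bn$rvar[c] + bn$eps) + bn$beta[c]
  }
  out
}

# The main block, written as a straight line of the nine defining steps.
naiveBlockOracle <- function(blk, x) {
  p1 <- naiveBn(naiveConv(x, blk$gc3$w, 1, blk$gc3$groups), blk$bnA)
  p2 <- naiveBn(naiveConv(x, blk$gc1$w, 1, blk$gc1$groups), blk$bnB)
  cc <- array(c(p1, p2), dim = c(dim(p1)[1:2], dim(p1)[3] + dim(p2)[3]))
  e <- naiveConv(cc, blk$expand$w, 1, blk$expand$groups)
  eg <- e * pnorm(e)
  s <- naiveBn(naiveConv(eg, blk$squeeze$w, 1, blk$squeeze$groups), blk$bnC)
  r1 <- x + s
  g <- naiveConv(r1, blk$brG$w, 1, blk$brG$groups)
  g <- g * pnorm(g)
  r <- naiveConv(r1, blk$brR$w, 1, blk$brR$groups)
  r[r < 0] <- 0
  fu <- naiveBn(g + r, blk$bnD)
  r1 + fu
}

# Replace one block's weights and batch-norm parameters/statistics with
# random values (inference-mode comparisons need non-trivial running
# statistics).
randomizeBlock <- function(model, stage = 1L, block = 1L, seed = 1L) {
  set.seed(seed)
  L <- model@layers
  blk <- L$stages[[stage]]$blocks[[block]]
  for (nm in c("gc3", "gc1", "expand", "squeeze", "brG", "brR")) {
    blk[[nm]]$w <- array(rnorm(length(blk[[nm]]$w), sd = 0.5),
                         dim = dim(blk[[nm]]$w))
  }
  for (nm in c("bnA", "bnB", "bnC", "bnD")) {
    cn <- length(blk[[nm]]$gamma)
    blk[[nm]]$gamma <- rnorm(cn, 1, 0.2)
    blk[[nm]]$beta <- rnorm(cn, 0, 0.2)
    blk[[nm]]$rmean <- rnorm(cn, 0, 0.3)
    blk[[nm]]$rvar <- runif(cn, 0.5, 1.5)
  }
  L$stages[[stage]]$blocks[[block]] <- blk
  model@layers <- L
  model
}

# Zero every convolution inside one block (batch norm keeps its identity
# defaults), under which the block must be an exact identity map.
zeroBlock <- function(model, stage = 1L, block = 1L) {
  L <- model@layers
  blk <- L$stages[[stage]]$blocks[[block]]
  for (nm in c("gc3", "gc1", "expand", "squeeze", "brG", "brR")) {
    blk[[nm]]$w <- blk[[nm]]$w * 0
  }
  L$stages[[stage]]$blocks[[block]] <- blk
  model@layers <- L
  model
}

randomValidConfig <- function(seed) {
  set.seed(seed)
  f1 <- sample(c(8L, 16L), 1)
  ns <- sample(2:3, 1)
  widths <- f1 * 2L^(0:(ns - 1))
  sg <- sample(c(TRUE, FALSE), 1)
  cpg <- if (sg) 2L else sample(c(1L, 2L), 1)
  inp <- sample(c(32L, 48L, 64L), 1)
  macnextConfig(
    inputHeight = inp, inputWidth = inp,
    stageWidths = widths, stageRepeats = sample(1:2, ns, replace = TRUE),
    channelsPerGroup = cpg,
    expansionGrouped = sample(c(TRUE, FALSE), 1),
    squeezeGrouped = sg,
    numClasses = sample(3:6, 1), initSeed = seed
  )
}

# Metrics recomputed straight from label vectors (not from the package's
# confusion matrix).
oracleMetricsFromLabels <- function(true, pred, nclass) {
  total <- length(true)
  out <- NULL
  for (c in seq_len(nclass)) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- rbind(out, c(acc = (tp + tn) / total, prec = prec, rec = rec,
                        f1 = f1))
  }
  list(perClass = out, overall = mean(true == pred),
       macro = colMeans(out)[2:4])
}

cmToLabels <- function(cm) {
  n <- nrow(cm)
  true <- integer(0); pred <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (cm[i, j] > 0) {
      true <- c(true, rep(i, cm[i, j]))
      pred <- c(pred, rep(j, cm[i, j]))
    }
  }
  list(true = true, pred = pred)
}

# Mann-Whitney AUC by exhaustive pair counting (ties count one half).
aucByPairCounting <- function(scores, positive) {
  ps <- scores[positive]
  ng <- scores[!positive]
  conc <- 0
  for (a in ps) conc <- conc + sum(a > ng) + 0.5 * sum(a == ng)
  conc / (length(ps) * length(ng))
}

# Small in-memory synthetic classification dataset rendered from distinct
# colony specs; used by the training tests.
makeTinyDataset <- function(nPerClass = 24L, size = 32L, seed = 99L,
                            classRows = c(2L, 5L, 10L, 20L)) {
  specs <- defaultClassSpecs()[classRows, ]
  nc <- length(classRows)
  x <- array(0, dim = c(size, size, 3L, nc * nPerClass))
  y <- integer(nc * nPerClass)
  k <- 0L
  for (ci in seq_len(nc)) {
    for (j in seq_len(nPerClass)) {
      k <- k + 1L
      x[, , , k] <- renderPlateImage(specs[ci, ], size, size,
                                     seed * 1000L + ci * 100L + j)
      y[k] <- ci
    }
  }
  list(x = x, y = y, nClasses = nc)
}

tinyNetConfig <- function(size = 32L, nClasses = 4L, initSeed = 7L) {
  macnextConfig(
    inputHeight = size, inputWidth = size,
    stageWidths = c(8L, 16L), stageRepeats = c(1L, 1L),
    numClasses = nClasses, initSeed = initSeed
  )
}
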