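# Network assembly and the forward/backward passes.
#
# Stage layout (matching the architecture's transition table): stem ->
# [stage s: stageRepeats[s] main blocks at width F[s]; a stride-2
# downsampling layer after every stage except the last] -> GAP -> FC ->
# softmax. Feature tensors are H x W x C x N arrays.

.groupsFor <- function(cin, cpg) cin %/% cpg

.buildBlock <- function(f, cfg) {
  cpg <- cfg@channelsPerGroup
  g <- .groupsFor(f, cpg)
  g2 <- .groupsFor(2L * f, cpg)
  eps <- cfg@bnEpsilon
  list(
    gc3 = .convLayer(3L, f, f, 1L, g),
    bnA = .bnLayer(f, eps),
    gc1 = .convLayer(1L, f, f, 1L, g),
    bnB = .bnLayer(f, eps),
    expand = .convLayer(1L, 2L * f, 2L * f, 1L,
                        if (cfg@expansionGrouped) g2 else 1L),
    squeeze = .convLayer(1L, 2L * f, f, 1L,
                         if (cfg@squeezeGrouped) g2 else 1L),
    bnC = .bnLayer(f, eps),
    brG = .convLayer(1L, f, f, 1L, g),
    brR = .convLayer(1L, f, f, 1L, g),
    bnD = .bnLayer(f, eps)
  )
}

#' Build a MACNeXt network
#'
#' Instantiates every layer of the network described by a
#' [MACNeXtConfig-class]: the two-convolution stem, the per-stage main
#' blocks with their dual GELU/ReLU activation branches, the stride-2
#' grouped downsampling layers between stages, and the GAP + fully
#' connected + softmax head. All weights are drawn deterministically from
#' `config@initSeed` (fan-in-scaled normal for convolutions, fan-based
#' uniform for the FC layer); two builds from the same seed are
#' bit-identical.
#'
#' @param config a [MACNeXtConfig-class]; invalid configurations are
#'   rejected with a message naming the violated invariant.
#' @return a [MACNeXtModel-class].
#' @examples
#' cfg <- macnextConfig(
#'   inputHeight = 64, inputWidth = 64,
#'   stageWidths = c(16, 32), stageRepeats = c(1, 1), numClasses = 4
#' )
#' model <- buildModel(cfg)
#' model
#' @export
buildModel <- function(config) {
  validObject(config)
  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(config@initSeed)

  eps <- config@bnEpsilon
  cpg <- config@channelsPerGroup
  sw <- config@stemWidths
  stem <- list(
    conv1 = .convLayer(3L, config@inputChannels, sw[1L], 2L, 1L),
    bn1 = .bnLayer(sw[1L], eps),
    conv2 = .convLayer(3L, sw[1L], sw[2L], 2L, .groupsFor(sw[1L], cpg)),
    bn2 = .bnLayer(sw[2L], eps)
  )

  nstage <- length(config@stageWidths)
  stages <- vector("list", nstage)
  for (s in seq_len(nstage)) {
    f <- config@stageWidths[s]
    blocks <- lapply(seq_len(config@stageRepeats[s]),
                     function(i) .buildBlock(f, config))
    down <- NULL
    if (s < nstage) {
      down <- list(
        conv = .convLayer(3L, f, 2L * f, 2L, .groupsFor(f, cpg)),
        bn = .bnLayer(2L * f, eps)
      )
    }
    stages[[s]] <- list(blocks = blocks, down = down)
  }

  flast <- config@stageWidths[nstage]
  head <- .fcLayer(flast, config@numClasses)

  new("MACNeXtModel", config = config,
      layers = list(stem = stem, stages = stages, head = head))
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.as4d <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("feature tensors must be H x W x C or H x W x C x N arrays")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

.checkTensor <- function(x, channels = NULL, what = "input") {
  if (!all(is.finite(x))) stop("non-finite values in ", what, " tensor")
  if (!is.null(channels) && dim(x)[3L] != channels) {
    stop(sprintf("%s has %d channels, expected %d", what, dim(x)[3L],
                 channels))
  }
  invisible(x)
}

.concatChannels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# ---- stem ----

.stemForwardFull <- function(stem, x, training = FALSE) {
  c1 <- .convForward(stem$conv1, x)
  b1 <- .bnForward(stem$bn1, c1, training)
  c2 <- .convForward(stem$conv2, b1$out)
  gg <- .gelu(c2)
  b2 <- .bnForward(stem$bn2, gg, training)
  stem$bn1 <- b1$layer
  stem$bn2 <- b2$layer
  list(out = b2$out, stem = stem,
       cache = list(x = x, c1 = c1, bn1 = b1, bn2o = b2, c2 = c2, g = gg))
}

.stemBackward <- function(stem, cache, dout) {
  bn2 <- .bnBackward(stem$bn2, cache$g, cache$bn2o, dout)
  dg <- bn2$dx * .geluGrad(cache$c2)
  cv2 <- .convBackward(stem$conv2, cache$bn1$out, dg)
  bn1 <- .bnBackward(stem$bn1, cache$c1, cache$bn1, cv2$dx)
  cv1 <- .convBackward(stem$conv1, cache$x, bn1$dx)
  list(dx = cv1$dx, grads = list(
    conv1.w = cv1$dw, bn1.gamma = bn1$dgamma, bn1.beta = bn1$dbeta,
    conv2.w = cv2$dw, bn2.gamma = bn2$dgamma, bn2.beta = bn2$dbeta
  ))
}

# ---- main block ----

.blockForwardFull <- function(blk, x, training = FALSE) {
  p1 <- .convForward(blk$gc3, x)
  b1 <- .bnForward(blk$bnA, p1, training)
  p2 <- .convForward(blk$gc1, x)
  b2 <- .bnForward(blk$bnB, p2, training)
  cc <- .concatChannels(b1$out, b2$out)
  e <- .convForward(blk$expand, cc)
  eg <- .gelu(e)
  s <- .convForward(blk$squeeze, eg)
  b3 <- .bnForward(blk$bnC, s, training)
  r1 <- x + b3$out
  g1 <- .convForward(blk$brG, r1)
  gg <- .gelu(g1)
  r2 <- .convForward(blk$brR, r1)
  rr <- .relu(r2)
  fu <- gg + rr
  b4 <- .bnForward(blk$bnD, fu, training)
  y <- r1 + b4$out
  blk$bnA <- b1$layer
  blk$bnB <- b2$layer
  blk$bnC <- b3$layer
  blk$bnD <- b4$layer
  list(out = y, blk = blk,
       cache = list(x = x, p1 = p1, p2 = p2, bn1 = b1, bn2 = b2, cc = cc,
                    e = e, eg = eg, s = s, bn3 = b3, r1 = r1, g1 = g1,
                    r2 = r2, fu = fu, bn4 = b4))
}

.blockBackwardFull <- function(blk, cache, dy) {
  f <- blk$gc3$cout
  dr1 <- dy
  bn4 <- .bnBackward(blk$bnD, cache$fu, cache$bn4, dy)
  dg1 <- bn4$dx * .geluGrad(cache$g1)
  dr2 <- bn4$dx * .reluGrad(cache$r2)
  cg <- .convBackward(blk$brG, cache$r1, dg1)
  cr <- .convBackward(blk$brR, cache$r1, dr2)
  dr1 <- dr1 + cg$dx + cr$dx

  dx <- dr1
  bn3 <- .bnBackward(blk$bnC, cache$s, cache$bn3, dr1)
  cs <- .convBackward(blk$squeeze, cache$eg, bn3$dx)
  de <- cs$dx * .geluGrad(cache$e)
  ce <- .convBackward(blk$expand, cache$cc, de)
  dp1o <- ce$dx[, , seq_len(f), , drop = FALSE]
  dp2o <- ce$dx[, , f + seq_len(f), , drop = FALSE]
  bn1 <- .bnBackward(blk$bnA, cache$p1, cache$bn1, dp1o)
  bn2 <- .bnBackward(blk$bnB, cache$p2, cache$bn2, dp2o)
  c3 <- .convBackward(blk$gc3, cache$x, bn1$dx)
  c1 <- .convBackward(blk$gc1, cache$x, bn2$dx)
  dx <- dx + c3$dx + c1$dx

  list(dx = dx, grads = list(
    gc3.w = c3$dw, bnA.gamma = bn1$dgamma, bnA.beta = bn1$dbeta,
    gc1.w = c1$dw, bnB.gamma = bn2$dgamma, bnB.beta = bn2$dbeta,
    expand.w = ce$dw, squeeze.w = cs$dw,
    bnC.gamma = bn3$dgamma, bnC.beta = bn3$dbeta,
    brG.w = cg$dw, brR.w = cr$dw,
    bnD.gamma = bn4$dgamma, bnD.beta = bn4$dbeta
  ))
}

# ---- downsampling ----

.downForwardFull <- function(down, x, training = FALSE) {
  cv <- .convForward(down$conv, x)
  bn <- .bnForward(down$bn, cv, training)
  down$bn <- bn$layer
  list(out = bn$out, down = down, cache = list(x = x, cv = cv, bn = bn))
}

.downBackward <- function(down, cache, dout) {
  bn <- .bnBackward(down$bn, cache$cv, cache$bn, dout)
  cv <- .convBackward(down$conv, cache$x, bn$dx)
  list(dx = cv$dx, grads = list(
    conv.w = cv$dw, bn.gamma = bn$dgamma, bn.beta = bn$dbeta
  ))
}

# ---- head ----

.headForwardFull <- function(head, x) {
  m <- .gap(x)                       # C x N
  z <- crossprod(head$w, m) + head$b # n x N
  p <- .softmax(z)
  list(probs = p, cache = list(xdim = dim(x), m = m, z = z))
}

.headBackward <- function(head, cache, dz) {
  dw <- cache$m %*% t(dz)
  db <- rowSums(dz)
  dm <- head$w %*% dz
  dx <- .gapBackward(dm, cache$xdim)
  list(dx = dx, grads = list(w = dw, b = db))
}

# ---- full model ----

.modelForwardFull <- function(model, x, training = FALSE) {
  L <- model@layers
  st <- .stemForwardFull(L$stem, x, training)
  L$stem <- st$stem
  caches <- list(stem = st$cache, stages = list())
  t <- st$out
  for (s in seq_along(L$stages)) {
    sc <- list(blocks = list(), down = NULL)
    for (b in seq_along(L$stages[[s]]$blocks)) {
      bf <- .blockForwardFull(L$stages[[s]]$blocks[[b]], t, training)
      L$stages[[s]]$blocks[[b]] <- bf$blk
      sc$blocks[[b]] <- bf$cache
      t <- bf$out
    }
    if (!is.null(L$stages[[s]]$down)) {
      df <- .downForwardFull(L$stages[[s]]$down, t, training)
      L$stages[[s]]$down <- df$down
      sc$down <- df$cache
      t <- df$out
    }
    caches$stages[[s]] <- sc
  }
  hf <- .headForwardFull(L$head, t)
  caches$head <- hf$cache
  model@layers <- L
  list(probs = hf$probs, caches = caches, model = model)
}

.modelBackwardFull <- function(model, caches, dz) {
  L <- model@layers
  grads <- list()
  hb <- .headBackward(L$head, caches$head, dz)
  grads[["head.w"]] <- hb$grads$w
  grads[["head.b"]] <- hb$grads$b
  dt <- hb$dx
  for (s in rev(seq_along(L$stages))) {
    if (!is.null(L$stages[[s]]$down)) {
      db <- .downBackward(L$stages[[s]]$down, caches$stages[[s]]$down, dt)
      for (nm in names(db$grads)) {
        grads[[sprintf("stage%d.down.%s", s, nm)]] <- db$grads[[nm]]
      }
      dt <- db$dx
    }
    for (b in rev(seq_along(L$stages[[s]]$blocks))) {
      bb <- .blockBackwardFull(L$stages[[s]]$blocks[[b]],
                               caches$stages[[s]]$blocks[[b]], dt)
      for (nm in names(bb$grads)) {
        grads[[sprintf("stage%d.block%d.%s", s, b, nm)]] <- bb$grads[[nm]]
      }
      dt <- bb$dx
    }
  }
  sb <- .stemBackward(L$stem, caches$stem, dt)
  for (nm in names(sb$grads)) grads[[sprintf("stem.%s", nm)]] <- sb$grads[[nm]]
  list(grads = grads, dx = sb$dx)
}

# Named flat list of the model's learnable arrays (running BN statistics are
# buffers, not parameters, and are excluded).
.collectParams <- function(model) {
  L <- model@layers
  out <- list()
  put <- function(name, v) out[[name]] <<- v
  put("stem.conv1.w", L$stem$conv1$w)
  put("stem.bn1.gamma", L$stem$bn1$gamma)
  put("stem.bn1.beta", L$stem$bn1$beta)
  put("stem.conv2.w", L$stem$conv2$w)
  put("stem.bn2.gamma", L$stem$bn2$gamma)
  put("stem.bn2.beta", L$stem$bn2$beta)
  for (s in seq_along(L$stages)) {
    for (b in seq_along(L$stages[[s]]$blocks)) {
      blk <- L$stages[[s]]$blocks[[b]]
      pre <- sprintf("stage%d.block%d", s, b)
      put(paste0(pre, ".gc3.w"), blk$gc3$w)
      put(paste0(pre, ".bnA.gamma"), blk$bnA$gamma)
      put(paste0(pre, ".bnA.beta"), blk$bnA$beta)
      put(paste0(pre, ".gc1.w"), blk$gc1$w)
      put(paste0(pre, ".bnB.gamma"), blk$bnB$gamma)
      put(paste0(pre, ".bnB.beta"), blk$bnB$beta)
      put(paste0(pre, ".expand.w"), blk$expand$w)
      put(paste0(pre, ".squeeze.w"), blk$squeeze$w)
      put(paste0(pre, ".bnC.gamma"), blk$bnC$gamma)
      put(paste0(pre, ".bnC.beta"), blk$bnC$beta)
      put(paste0(pre, ".brG.w"), blk$brG$w)
      put(paste0(pre, ".brR.w"), blk$brR$w)
      put(paste0(pre, ".bnD.gamma"), blk$bnD$gamma)
      put(paste0(pre, ".bnD.beta"), blk$bnD$beta)
    }
    if (!is.null(L$stages[[s]]$down)) {
      pre <- sprintf("stage%d.down", s)
      put(paste0(pre, ".conv.w"), L$stages[[s]]$down$conv$w)
      put(paste0(pre, ".bn.gamma"), L$stages[[s]]$down$bn$gamma)
      put(paste0(pre, ".bn.beta"), L$stages[[s]]$down$bn$beta)
    }
  }
  put("head.w", L$head$w)
  put("head.b", L$head$b)
  out
}

# Write a flat named parameter list back into the nested layers.
.setParams <- function(model, params) {
  L <- model@layers
  take <- function(name) params[[name]]
  L$stem$conv1$w <- take("stem.conv1.w")
  L$stem$bn1$gamma <- take("stem.bn1.gamma")
  L$stem$bn1$beta <- take("stem.bn1.beta")
  L$stem$conv2$w <- take("stem.conv2.w")
  L$stem$bn2$gamma <- take("stem.bn2.gamma")
  L$stem$bn2$beta <- take("stem.bn2.beta")
  for (s in seq_along(L$stages)) {
    for (b in seq_along(L$stages[[s]]$blocks)) {
      pre <- sprintf("stage%d.block%d", s, b)
      blk <- L$stages[[s]]$blocks[[b]]
      blk$gc3$w <- take(paste0(pre, ".gc3.w"))
      blk$bnA$gamma <- take(paste0(pre, ".bnA.gamma"))
      blk$bnA$beta <- take(paste0(pre, ".bnA.beta"))
      blk$gc1$w <- take(paste0(pre, ".gc1.w"))
      blk$bnB$gamma <- take(paste0(pre, ".bnB.gamma"))
      blk$bnB$beta <- take(paste0(pre, ".bnB.beta"))
      blk$expand$w <- take(paste0(pre, ".expand.w"))
      blk$squeeze$w <- take(paste0(pre, ".squeeze.w"))
      blk$bnC$gamma <- take(paste0(pre, ".bnC.gamma"))
      blk$bnC$beta <- take(paste0(pre, ".bnC.beta"))
      blk$brG$w <- take(paste0(pre, ".brG.w"))
      blk$brR$w <- take(paste0(pre, ".brR.w"))
      blk$bnD$gamma <- take(paste0(pre, ".bnD.gamma"))
      blk$bnD$beta <- take(paste0(pre, ".bnD.beta"))
      L$stages[[s]]$blocks[[b]] <- blk
    }
    if (!is.null(L$stages[[s]]$down)) {
      pre <- sprintf("stage%d.down", s)
      L$stages[[s]]$down$conv$w <- take(paste0(pre, ".conv.w"))
      L$stages[[s]]$down$bn$gamma <- take(paste0(pre, ".bn.gamma"))
      L$stages[[s]]$down$bn$beta <- take(paste0(pre, ".bn.beta"))
    }
  }
  L$head$w <- take("head.w")
  L$head$b <- take("head.b")
  model@layers <- L
  model
}

# ---- public component operations ----

#' Run the stem block
#'
#' Applies the two stem convolutions (3x3 stride 2, then grouped 3x3
#' stride 2 with GELU) with their batch normalizations in inference mode.
#' Spatial sides shrink to `ceiling(side / 4)`; the channel count becomes
#' the second stem width (96 in the reference network, turning a
#' 224x224x3 image into a 56x56x96 map).
#'
#' @param model a [MACNeXtModel-class].
#' @param x an `H x W x C` or `H x W x C x N` numeric array; `C` must equal
#'   the configured input channel count and all values must be finite.
#' @return the stem output tensor (always 4-D).
#' @export
stemForward <- function(model, x) {
  stopifnot(is(model, "MACNeXtModel"))
  x <- .as4d(x)
  .checkTensor(x, model@config@inputChannels, "image")
  if (any(dim(x)[1:2] < 4L)) stop("spatial sides must be at least 4")
  .stemForwardFull(model@layers$stem, x, training = FALSE)$out
}

#' Run one main block
#'
#' Applies a single dual-activation residual block of the network in
#' inference mode: parallel grouped 3x3/1x1 convolutions with batch norm,
#' channel concatenation to twice the width, 1x1 expansion, GELU, 1x1
#' squeeze back with batch norm, a residual addition, parallel grouped 1x1
#' GELU and ReLU branches fused by addition and batch norm, and a final
#' residual addition. Output shape equals input shape.
#'
#' @param model a [MACNeXtModel-class].
#' @param x input tensor whose channel count equals the stage width.
#' @param stage,block stage index and block index within the stage.
#' @return the block output tensor.
#' @export
blockForward <- function(model, x, stage = 1L, block = 1L) {
  stopifnot(is(model, "MACNeXtModel"))
  blk <- model@layers$stages[[stage]]$blocks[[block]]
  x <- .as4d(x)
  .checkTensor(x, blk$gc3$cin, "block input")
  .blockForwardFull(blk, x, training = FALSE)$out
}

#' Run a downsampling layer
#'
#' Grouped 3x3 convolution with stride 2 followed by batch norm (inference
#' mode): spatial sides become `ceiling(side / 2)` and the channel count
#' doubles.
#'
#' @inheritParams blockForward
#' @param stage stage whose trailing downsampling layer to apply.
#' @return the downsampled tensor.
#' @export
downsampleForward <- function(model, x, stage = 1L) {
  stopifnot(is(model, "MACNeXtModel"))
  down <- model@layers$stages[[stage]]$down
  if (is.null(down)) stop("stage ", stage, " has no downsampling layer")
  x <- .as4d(x)
  .checkTensor(x, down$conv$cin, "downsampling input")
  .downForwardFull(down, x, training = FALSE)$out
}

#' Run the classification head
#'
#' Global average pooling over the spatial dimensions, a fully connected
#' map to the class logits, and softmax.
#'
#' @inheritParams blockForward
#' @param x tensor whose channel count equals the final stage width.
#' @return a list with `probabilities` (N x n matrix, rows summing to 1)
#'   and `predicted` (integer class index per sample).
#' @export
headForward <- function(model, x) {
  stopifnot(is(model, "MACNeXtModel"))
  cfg <- model@config
  x <- .as4d(x)
  flast <- cfg@stageWidths[length(cfg@stageWidths)]
  .checkTensor(x, flast, "head input")
  hf <- .headForwardFull(model@layers$head, x)
  list(probabilities = t(hf$probs),
       predicted = apply(hf$probs, 2L, which.max))
}

#' Class probabilities for a batch of images
#'
#' Full inference-mode forward pass, processed in mini-batches.
#'
#' @param model a [MACNeXtModel-class].
#' @param x image array `H x W x C x N` (or a single `H x W x C` image).
#' @param batchSize mini-batch size used for the forward passes.
#' @return an `N x numClasses` probability matrix.
#' @export
predictProba <- function(model, x, batchSize = 64L) {
  x <- .as4d(x)
  .checkTensor(x, model@config@inputChannels, "image")
  n <- dim(x)[4L]
  out <- matrix(0, n, model@config@numClasses)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    fw <- .modelForwardFull(model, x[, , , i:j, drop = FALSE],
                            training = FALSE)
    out[i:j, ] <- t(fw$probs)
    i <- j + 1L
  }
  out
}

#' @describeIn predictProba hard class predictions (integer indices).
#' @export
predictClasses <- function(model, x, batchSize = 64L) {
  max.col(predictProba(model, x, batchSize), ties.method = "first")
}

#' Save / load a model checkpoint
#'
#' Serializes the full model (configuration, weights and batch-norm running
#' statistics). The round trip is bit-exact: a reloaded model produces
#' identical outputs on any fixed batch.
#'
#' @param model a [MACNeXtModel-class].
#' @param path file path for the checkpoint.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "MACNeXtModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!is(model, "MACNeXtModel")) stop("not a MACNeXt checkpoint: ", path)
  validObject(model@config)
  model
}

setMethod("show", "MACNeXtModel", function(object) {
  cfg <- object@config
  pc <- sum(vapply(.collectParams(object), length, integer(1)))
  cat("MACNeXt network\n")
  cat(sprintf("  stages: %s (repeats %s)\n",
              paste(cfg@stageWidths, collapse = "/"),
              paste(cfg@stageRepeats, collapse = "/")))
  cat(sprintf("  classes: %d\n", cfg@numClasses))
  cat(sprintf("  learnable parameters: %s\n",
              format(pc, big.mark = ",")))
  invisible(NULL)
})
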