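# Training protocol: stratified two-stage splitting, momentum SGD on the
# cross-entropy loss at a constant learning rate, per-epoch logging, and
# evaluation feeding the metrics module.

#' Stratified train/validation/test split
#'
#' Two nested splits reproduce the study protocol: first `testFraction` of
#' the data is held out (by `floor`), then the validation share is taken
#' from the remainder (`valFraction / (trainFraction + valFraction)`, again
#' by `floor`), with everything left going to training. With the default
#' 64/16/20 fractions, 100 samples of one class split 64/16/20 and 25
#' samples split 16/4/5. Stratification applies the rule within each class;
#' the result is deterministic given `config@seed`.
#'
#' @param classIds per-sample class labels (any atomic vector).
#' @param config a [TrainConfig-class].
#' @param stratified split within each class (default) or globally.
#' @return a factor of levels `train`, `val`, `test` (one per sample) with
#'   attribute `stratified`.
#' @export
splitDataset <- function(classIds, config = trainConfig(),
                         stratified = TRUE) {
  validObject(config)
  n <- length(classIds)
  if (n < 5L) stop("need at least 5 samples to split")
  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(config@seed)

  part <- character(n)
  assign1 <- function(idx) {
    m <- length(idx)
    idx <- idx[sample.int(m)]
    ntest <- floor(m * config@testFraction)
    rest <- m - ntest
    nval <- floor(rest * config@valFraction /
                    (config@trainFraction + config@valFraction))
    p <- rep("train", m)
    if (ntest > 0) p[seq_len(ntest)] <- "test"
    if (nval > 0) p[ntest + seq_len(nval)] <- "val"
    part[idx] <<- p
  }
  if (stratified) {
    for (cl in sort(unique(as.character(classIds)))) {
      idx <- which(as.character(classIds) == cl)
      if (length(idx) < 5L) {
        stop(sprintf(
          "class '%s' has only %d sample(s); at least 5 are required for a stratified split",
          cl, length(idx)
        ))
      }
      assign1(idx)
    }
  } else {
    assign1(seq_len(n))
  }
  out <- factor(part, levels = c("train", "val", "test"))
  attr(out, "stratified") <- stratified
  out
}

.crossEntropy <- function(probs, labels) {
  # probs: n x N, labels in 1..n
  p <- probs[cbind(labels, seq_along(labels))]
  -mean(log(pmax(p, 1e-12)))
}

# Epoch ordering. Plain mode shuffles the training indices; balanced mode
# interleaves the classes (one draw per class per round, cycling each
# class's shuffled pool) so every mini-batch holds a near-uniform class mix
# regardless of the dataset's imbalance.
.epochOrder <- function(labels, idx, balanced) {
  if (!balanced) return(idx[sample.int(length(idx))])
  classes <- sort(unique(labels[idx]))
  pools <- lapply(classes, function(cl) {
    p <- idx[labels[idx] == cl]
    p[sample.int(length(p))]
  })
  pos <- rep(1L, length(pools))
  out <- integer(0)
  rounds <- ceiling(length(idx) / length(classes))
  for (r in seq_len(rounds)) {
    ord <- sample.int(length(classes))
    for (ci in ord) {
      if (pos[ci] > length(pools[[ci]])) {
        pools[[ci]] <- pools[[ci]][sample.int(length(pools[[ci]]))]
        pos[ci] <- 1L
      }
      out <- c(out, pools[[ci]][pos[ci]])
      pos[ci] <- pos[ci] + 1L
    }
  }
  out[seq_len(length(idx))]
}

#' Train a MACNeXt network
#'
#' Momentum SGD on the softmax cross-entropy at a constant learning rate,
#' with weight decay applied to convolution and fully connected weights
#' (batch-norm affine parameters and the FC bias are not decayed). Batch
#' norm runs in training mode during updates and inference mode during the
#' per-epoch validation pass. The run is fully deterministic given
#' `config@seed` (and the model's `initSeed`).
#'
#' @param model a freshly built (or resumed) [MACNeXtModel-class].
#' @param images `H x W x C x N` array of all images, values in `[0, 1]`.
#' @param labels integer class labels in `1..numClasses`.
#' @param split a [splitDataset()] factor; `train` rows are optimized,
#'   `val` rows scored each epoch.
#' @param config a [TrainConfig-class].
#' @param outDir optional directory for `log.csv` and the final/best
#'   checkpoints.
#' @param verbose print one line per epoch.
#' @return a list: `model` (final weights), `bestModel` (highest validation
#'   accuracy), `log` (data.frame epoch/train_loss/train_acc/val_loss/
#'   val_acc).
#' @export
trainModel <- function(model, images, labels, split, config = trainConfig(),
                       outDir = NULL, verbose = FALSE) {
  stopifnot(is(model, "MACNeXtModel"))
  validObject(config)
  labels <- as.integer(labels)
  n <- model@config@numClasses
  if (max(labels) > n || min(labels) < 1L) {
    stop("labels outside 1..", n, " (model class count mismatch)")
  }
  trainIdx <- which(split == "train")
  valIdx <- which(split == "val")
  if (length(trainIdx) == 0L) stop("empty training partition")

  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(config@seed)

  params <- .collectParams(model)
  vel <- lapply(params, function(p) p * 0)
  decay <- grepl("\\.w$", names(params)) & !grepl("^head\\.b", names(params))
  lr <- config@learningRate
  mom <- config@momentum
  wd <- config@weightDecay

  logRows <- list()
  bestVal <- -Inf
  bestModel <- model

  for (epoch in seq_len(config@epochs)) {
    ord <- .epochOrder(labels, trainIdx, config@balancedBatches)
    nb <- ceiling(length(ord) / config@batchSize)
    eLoss <- 0
    eAcc <- 0
    eCount <- 0L
    for (b in seq_len(nb)) {
      lo <- (b - 1L) * config@batchSize + 1L
      hi <- min(b * config@batchSize, length(ord))
      bidx <- ord[lo:hi]
      xb <- images[, , , bidx, drop = FALSE]
      yb <- labels[bidx]
      fw <- .modelForwardFull(model, xb, training = TRUE)
      model <- fw$model
      probs <- fw$probs
      m <- length(bidx)
      eLoss <- eLoss + .crossEntropy(probs, yb) * m
      eAcc <- eAcc + sum(max.col(t(probs), ties.method = "first") == yb)
      eCount <- eCount + m

      hot <- matrix(0, n, m)
      hot[cbind(yb, seq_len(m))] <- 1
      dz <- (probs - hot) / m
      bw <- .modelBackwardFull(model, fw$caches, dz)
      grads <- bw$grads
      for (nm in names(params)) {
        g <- grads[[nm]]
        if (decay[match(nm, names(params))]) g <- g + wd * params[[nm]]
        vel[[nm]] <- mom * vel[[nm]] + g
        params[[nm]] <- params[[nm]] - lr * vel[[nm]]
      }
      model <- .setParams(model, params)
    }
    trainLoss <- eLoss / eCount
    trainAcc <- eAcc / eCount

    valLoss <- NA_real_
    valAcc <- NA_real_
    if (length(valIdx)) {
      vp <- predictProba(model, images[, , , valIdx, drop = FALSE],
                         batchSize = config@batchSize)
      valLoss <- .crossEntropy(t(vp), labels[valIdx])
      valAcc <- mean(max.col(vp, ties.method = "first") == labels[valIdx])
      if (valAcc > bestVal) {
        bestVal <- valAcc
        bestModel <- model
      }
    } else {
      bestModel <- model
    }
    logRows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = trainLoss, train_acc = trainAcc,
      val_loss = valLoss, val_acc = valAcc
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f  val loss %s acc %s",
        epoch, trainLoss, trainAcc,
        ifelse(is.na(valLoss), "--", sprintf("%.4f", valLoss)),
        ifelse(is.na(valAcc), "--", sprintf("%.4f", valAcc))
      ))
    }
  }
  log <- do.call(rbind, logRows)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(outDir, "log.csv"), row.names = FALSE)
    saveCheckpoint(model, file.path(outDir, "checkpoint_final.rds"))
    saveCheckpoint(bestModel, file.path(outDir, "checkpoint_best.rds"))
  }
  list(model = model, bestModel = bestModel, log = log)
}

#' Evaluate a trained network on a partition
#'
#' Inference-mode forward passes over the chosen samples; the predictions
#' feed [metricsReport()] verbatim.
#'
#' @param model a trained [MACNeXtModel-class].
#' @param images full image array.
#' @param labels integer labels in `1..numClasses`.
#' @param indices sample indices to evaluate (default: all).
#' @param classLabels class names for the report (default `"1".."n"`).
#' @param batchSize forward-pass batch size.
#' @return a list with `confusion`, `perClass`, `aggregate`, `auc` and a
#'   `predictions` data.frame (index, true, predicted, prob of predicted).
#' @export
evaluateModel <- function(model, images, labels, indices = NULL,
                          classLabels = NULL, batchSize = 64L) {
  labels <- as.integer(labels)
  n <- model@config@numClasses
  if (is.null(indices)) indices <- seq_along(labels)
  if (length(indices) == 0L) stop("empty evaluation partition")
  if (is.null(classLabels)) classLabels <- as.character(seq_len(n))
  probs <- predictProba(model, images[, , , indices, drop = FALSE],
                        batchSize = batchSize)
  colnames(probs) <- classLabels
  pred <- max.col(probs, ties.method = "first")
  rep <- metricsReport(classLabels[labels[indices]], classLabels[pred],
                       classLabels, probabilities = probs)
  predictions <- data.frame(
    index = indices,
    true = classLabels[labels[indices]],
    predicted = classLabels[pred],
    probability = probs[cbind(seq_along(pred), pred)],
    stringsAsFactors = FALSE
  )
  c(rep, list(predictions = predictions))
}
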