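# Split protocol, optimizer behaviour, determinism and the evaluation
# round trip, on small in-memory synthetic datasets.

test_that("a 100-sample class splits 64/16/20 and a 25-sample class splits 16/4/5", {
  s100 <- splitDataset(rep(1L, 100), trainConfig(seed = 3L))
  expect_identical(as.integer(table(s100)), c(64L, 16L, 20L))
  s25 <- splitDataset(rep(1L, 25), trainConfig(seed = 3L))
  expect_identical(as.integer(table(s25)), c(16L, 4L, 5L))
})

test_that("splits are disjoint, exhaustive, stratified within one sample, and deterministic", {
  set.seed(19)
  y <- sample(rep(1:4, c(40, 25, 9, 120)))
  cfg <- trainConfig(seed = 8L)
  s <- splitDataset(y, cfg)
  expect_identical(length(s), length(y))
  expect_false(anyNA(s))
  for (cl in 1:4) {
    nTest <- sum(s == "test" & y == cl)
    target <- 0.2 * sum(y == cl)
    expect_lte(abs(nTest - target), 1)
  }
  expect_identical(s, splitDataset(y, cfg))
  expect_false(identical(s, splitDataset(y, trainConfig(seed = 9L))))
})

test_that("a class below five samples aborts a stratified split naming the class", {
  y <- c(rep("abundant", 30), rep("rare", 3))
  expect_error(splitDataset(y, trainConfig()), "rare.*3 sample")
})

test_that("balanced mini-batches hold near-uniform class mixes despite imbalance", {
  ns <- asNamespace("macnext")
  y <- rep(1:4, c(500, 60, 30, 10))
  idx <- seq_along(y)
  set.seed(5)
  ord <- ns$.epochOrder(y, idx, balanced = TRUE)
  expect_identical(length(ord), length(idx))
  batch <- 128L
  for (b in seq_len(length(ord) %/% batch)) {
    counts <- tabulate(y[ord[((b - 1) * batch + 1):(b * batch)]], 4)
    expect_true(all(abs(counts - batch / 4) <= 2),
                label = sprintf("batch %d composition %s", b,
                                paste(counts, collapse = "/")))
  }
  plain <- ns$.epochOrder(y, idx, balanced = FALSE)
  expect_identical(sort(plain), idx)
})

test_that("identical seeds reproduce identical per-epoch logs", {
  data <- makeTinyDataset(nPerClass = 10L, size = 32L, seed = 7L)
  cfg <- tinyNetConfig(32L, data$nClasses, initSeed = 3L)
  tc <- trainConfig(epochs = 2L, batchSize = 16L, seed = 21L)
  split <- splitDataset(data$y, tc)
  run <- function() {
    trainModel(buildModel(cfg), data$x, data$y, split, tc)
  }
  a <- run()
  b <- run()
  expect_identical(a$log, b$log)
  expect_identical(asNamespace("macnext")$.collectParams(a$model),
                   asNamespace("macnext")$.collectParams(b$model))
})

test_that("training loss decreases over the first epochs (median across seeds)", {
  data <- makeTinyDataset(nPerClass = 12L, size = 32L, seed = 13L)
  drops <- vapply(1:3, function(s) {
    tc <- trainConfig(epochs = 3L, batchSize = 16L, seed = s)
    split <- splitDataset(data$y, tc)
    fit <- trainModel(buildModel(tinyNetConfig(32L, data$nClasses,
                                               initSeed = s)),
                      data$x, data$y, split, tc)
    fit$log$train_loss[1] - fit$log$train_loss[3]
  }, numeric(1))
  expect_gt(median(drops), 0)
})

test_that("training on a single small batch drives its accuracy to 100%", {
  data <- makeTinyDataset(nPerClass = 8L, size = 32L, seed = 5L)
  idx <- as.integer(sapply(1:4, function(c) which(data$y == c)[1:4]))
  x <- data$x[, , , idx, drop = FALSE]
  y <- data$y[idx]
  tc <- trainConfig(epochs = 60L, batchSize = 16L, seed = 2L,
                    weightDecay = 0)
  split <- factor(rep("train", 16), levels = c("train", "val", "test"))
  fit <- trainModel(buildModel(tinyNetConfig(32L, 4L, initSeed = 1L)),
                    x, y, split, tc)
  acc <- mean(predictClasses(fit$model, x) == y)
  expect_identical(acc, 1)
})

test_that("evaluateModel matches metrics recomputed from its own predictions", {
  data <- makeTinyDataset(nPerClass = 8L, size = 32L, seed = 23L)
  model <- buildModel(tinyNetConfig(32L, data$nClasses, initSeed = 2L))
  idx <- seq(1, length(data$y), by = 2)
  res <- evaluateModel(model, data$x, data$y, indices = idx)
  expect_identical(sum(res$confusion), length(idx))
  recomputed <- metricsReport(res$predictions$true, res$predictions$predicted,
                              rownames(res$confusion))
  expect_identical(res$confusion, recomputed$confusion)
  expect_equal(res$aggregate, recomputed$aggregate)
  expect_error(evaluateModel(model, data$x, data$y, indices = integer(0)),
               "empty")
})

test_that("analytic gradients match finite differences through the whole network", {
  ns <- asNamespace("macnext")
  cfg <- macnextConfig(
    inputHeight = 8L, inputWidth = 8L, stageWidths = c(4L, 8L),
    stageRepeats = c(1L, 1L), numClasses = 3L, initSeed = 3L
  )
  m <- buildModel(cfg)
  set.seed(7)
  N <- 2L
  x <- array(runif(8 * 8 * 3 * N), c(8, 8, 3, N))
  y <- c(1L, 3L)
  lossOf <- function(model) {
    p <- ns$.modelForwardFull(model, x, training = TRUE)$probs
    -mean(log(p[cbind(y, seq_len(N))]))
  }
  fw <- ns$.modelForwardFull(m, x, training = TRUE)
  hot <- matrix(0, 3, N)
  hot[cbind(y, 1:N)] <- 1
  bw <- ns$.modelBackwardFull(fw$model, fw$caches, (fw$probs - hot) / N)
  params <- ns$.collectParams(m)
  eps <- 1e-4
  check <- c("stem.conv1.w", "stage1.block1.gc3.w", "stage1.block1.expand.w",
             "stage1.block1.bnC.gamma", "stage1.down.conv.w",
             "stage2.block1.brR.w", "head.w", "head.b")
  for (nm in check) {
    for (i in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- lossOf(ns$.setParams(m, p2))
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      lm <- lossOf(ns$.setParams(m, p2))
      num <- (lp - lm) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-2,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})
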