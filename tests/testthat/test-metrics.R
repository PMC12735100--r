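# Confusion-matrix construction, the four one-vs-rest metrics, macro
# aggregation and multiclass AUC, each against independent oracles.

test_that("confusion matrix tallies true rows against predicted columns", {
  cm <- computeConfusion(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(as.integer(cm), c(1L, 0L, 1L, 1L))
  expect_identical(rownames(cm), c("A", "B"))

  perfect <- computeConfusion(rep(c("x", "y", "z"), c(4, 3, 3)),
                              rep(c("x", "y", "z"), c(4, 3, 3)))
  expect_identical(diag(perfect), c(x = 4L, y = 3L, z = 3L))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)

  expect_error(computeConfusion("A", "Q", c("A", "B")), "unknown label.*Q")
})

test_that("row sums equal per-class true counts on random label pairs", {
  set.seed(11)
  for (r in 1:5) {
    true <- sample(1:5, 200, replace = TRUE)
    pred <- sample(1:5, 200, replace = TRUE)
    cm <- computeConfusion(true, pred, 1:5)
    expect_identical(unname(rowSums(cm)), as.numeric(tabulate(true, 5)))
    expect_identical(sum(cm), 200L)
  }
})

test_that("the hand-worked 2x2 table gives the documented metric values", {
  cm <- matrix(c(8L, 1L, 2L, 9L), 2,
               dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  pc <- perClassMetrics(cm)
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(pc$recall[1], 0.8)
  expect_equal(pc$f1[1], 2 * (8 / 9 * 0.8) / (8 / 9 + 0.8))
  expect_equal(pc$accuracy[1], 0.85)
  agg <- aggregateMetrics(cm, pc)
  expect_equal(agg$accuracy, 17 / 20)
  # for two classes, both one-vs-rest accuracies equal the overall accuracy
  expect_equal(pc$accuracy[2], pc$accuracy[1])
  expect_equal(pc$accuracy[1], agg$accuracy)
})

test_that("a perfect diagonal yields all ones; empty classes are flagged, not NaN", {
  cm <- diag(c(5L, 3L, 2L))
  dimnames(cm) <- list(true = 1:3, predicted = 1:3)
  pc <- perClassMetrics(cm)
  expect_true(all(pc$accuracy == 1 & pc$precision == 1 &
                    pc$recall == 1 & pc$f1 == 1))
  expect_false(any(pc$degenerate))

  cm2 <- matrix(c(4L, 0L, 0L, 0L), 2,
                dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  pc2 <- perClassMetrics(cm2)
  expect_identical(pc2$precision[2], 0)
  expect_identical(pc2$recall[2], 0)
  expect_true(pc2$degenerate[2])
  expect_false(anyNA(pc2))

  one <- matrix(7L, 1, 1, dimnames = list(true = "A", predicted = "A"))
  agg1 <- aggregateMetrics(one)
  expect_equal(unlist(agg1[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("macro metrics are invariant under class permutation", {
  set.seed(21)
  cm <- matrix(rpois(25, 6), 5)
  dimnames(cm) <- list(true = letters[1:5], predicted = letters[1:5])
  p <- c(3, 5, 1, 4, 2)
  cmP <- cm[p, p]
  a <- aggregateMetrics(cm)
  b <- aggregateMetrics(cmP)
  expect_equal(a$f1, b$f1)
  expect_equal(a$precision, b$precision)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("metrics agree with a from-labels oracle on 50 random confusion matrices", {
  set.seed(33)
  for (r in 1:50) {
    n <- sample(2:6, 1)
    cm <- matrix(rpois(n * n, 4), n)
    if (sum(cm) == 0) cm[1, 1] <- 1
    dimnames(cm) <- list(true = seq_len(n), predicted = seq_len(n))
    lab <- cmToLabels(cm)
    want <- oracleMetricsFromLabels(lab$true, lab$pred, n)
    pc <- perClassMetrics(cm)
    agg <- aggregateMetrics(cm, pc)
    expect_equal(pc$accuracy, unname(want$perClass[, "acc"]),
                 tolerance = 1e-12)
    expect_equal(pc$precision, unname(want$perClass[, "prec"]),
                 tolerance = 1e-12)
    expect_equal(pc$recall, unname(want$perClass[, "rec"]),
                 tolerance = 1e-12)
    expect_equal(pc$f1, unname(want$perClass[, "f1"]), tolerance = 1e-12)
    expect_equal(agg$accuracy, want$overall, tolerance = 1e-12)
    expect_equal(agg$precision, unname(want$macro["prec"]),
                 tolerance = 1e-12)
  }
})

test_that("multiclass AUC matches pair counting on the 6-sample hand example", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  probs <- cbind(`0` = 1 - scores, `1` = scores)
  want1 <- aucByPairCounting(scores, labels == 1)
  expect_equal(want1, 8 / 9)
  expect_equal(multiclassAuc(labels, probs), 8 / 9)
})

test_that("AUC is 1 for perfect separation and 0.5 for constant scores", {
  labels <- rep(1:2, each = 5)
  perfect <- cbind(c(rep(0.9, 5), rep(0.1, 5)), c(rep(0.1, 5), rep(0.9, 5)))
  colnames(perfect) <- c("1", "2")
  expect_equal(multiclassAuc(labels, perfect), 1)
  flat <- matrix(0.5, 10, 2, dimnames = list(NULL, c("1", "2")))
  expect_equal(multiclassAuc(labels, flat), 0.5)
})

test_that("AUC agrees with pROC and pair counting on random score sets, and warns on absent classes", {
  set.seed(44)
  for (r in 1:10) {
    n <- 40
    labels <- sample(1:3, n, replace = TRUE)
    raw <- matrix(runif(n * 3), n, 3)
    probs <- raw / rowSums(raw)
    colnames(probs) <- as.character(1:3)
    per <- vapply(1:3, function(c) {
      aucByPairCounting(probs[, c], labels == c)
    }, numeric(1))
    expect_equal(multiclassAuc(labels, probs), mean(per), tolerance = 1e-12)
    pr <- vapply(1:3, function(c) {
      as.numeric(pROC::auc(pROC::roc(
        response = as.integer(labels == c), predictor = probs[, c],
        quiet = TRUE, direction = "<"
      )))
    }, numeric(1))
    expect_equal(mean(per), mean(pr), tolerance = 1e-12)
  }
  probs2 <- matrix(c(0.8, 0.1, 0.1, 0.2, 0.7, 0.1), 2, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(multiclassAuc(c("a", "b"), probs2), "absent.*c")
})

test_that("reports serialize to CSV and JSON with the stated orientation", {
  rep <- metricsReport(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                       c("A", "B"))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeMetricsCsv(rep, csv)
  got <- utils::read.csv(csv)
  expect_identical(nrow(got), 3L)
  expect_identical(got$class[3], "<macro>")

  ccsv <- withr::local_tempfile(fileext = ".csv")
  writeConfusionCsv(rep$confusion, ccsv)
  back <- utils::read.csv(ccsv)
  expect_identical(back$true, c("A", "B"))
  expect_identical(back$A, c(1L, 0L))

  js <- withr::local_tempfile(fileext = ".json")
  writeMetricsJson(rep, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_match(parsed$orientation, "rows = true")
  expect_equal(parsed$aggregate$accuracy, 3 / 4)
})
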