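# Confusion-matrix metrics. Rows of every confusion matrix index the true
# label, columns the predicted label. Per-class metrics are one-vs-rest:
# for class c the matrix collapses to TP/FP/TN/FN and
#   accuracy  = (TP + TN) / (TP + TN + FP + FN)
#   precision = TP / (TP + FP)
#   recall    = TP / (TP + FN)
#   F1        = 2 * precision * recall / (precision + recall)
# with zero-denominator cases reported as 0 and flagged. Aggregate
# precision/recall/F1 are macro (unweighted class means); overall accuracy
# is the diagonal sum over the total.

#' Build a confusion matrix
#'
#' @param true,predicted label vectors of equal length; every value must
#'   appear in `classLabels`.
#' @param classLabels ordered class names fixing row/column order. Defaults
#'   to the sorted union of observed labels.
#' @return an integer matrix with `dimnames` `list(true = ..., predicted
#'   = ...)`; entry `[i, j]` counts samples of true class i predicted as j.
#' @examples
#' computeConfusion(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
computeConfusion <- function(true, predicted, classLabels = NULL) {
  if (length(true) != length(predicted)) {
    stop("true and predicted labels must have equal length")
  }
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (is.null(classLabels)) classLabels <- sort(unique(c(true, predicted)))
  classLabels <- as.character(classLabels)
  bad <- setdiff(unique(c(true, predicted)), classLabels)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  tf <- factor(true, levels = classLabels)
  pf <- factor(predicted, levels = classLabels)
  cm <- table(tf, pf)
  m <- matrix(as.integer(cm), nrow = length(classLabels),
              dimnames = list(true = classLabels, predicted = classLabels))
  m
}

.checkConfusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("confusion matrix must be square")
  }
  if (any(cm < 0)) stop("confusion matrix entries must be nonnegative")
  invisible(cm)
}

#' Per-class one-vs-rest metrics
#'
#' @param cm a square confusion matrix (rows = true, columns = predicted).
#' @return a data.frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `tn`, `accuracy`, `precision`, `recall`, `f1`, and `degenerate`
#'   (TRUE where a zero denominator forced a metric to 0).
#' @examples
#' cm <- matrix(c(8, 1, 2, 9), 2, dimnames = list(
#'   true = c("A", "B"), predicted = c("A", "B")
#' ))
#' perClassMetrics(cm)
#' @export
perClassMetrics <- function(cm) {
  .checkConfusion(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    degenerate <- FALSE
    prec <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
      degenerate <- TRUE; 0
    }
    acc <- if (total > 0) (tp + tn) / total else { degenerate <- TRUE; 0 }
    data.frame(class = labels[i], tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = acc, precision = prec, recall = rec, f1 = f1,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Aggregate metrics
#'
#' Overall accuracy is the diagonal sum over the total; precision, recall
#' and F1 are aggregated over classes, macro (unweighted mean) by default
#' or weighted by per-class true counts.
#'
#' @param cm a square confusion matrix.
#' @param perClass optional precomputed [perClassMetrics()] result.
#' @param average `"macro"` or `"weighted"`.
#' @return a one-row data.frame: `accuracy`, `precision`, `recall`, `f1`,
#'   `average`.
#' @export
aggregateMetrics <- function(cm, perClass = NULL, average = "macro") {
  .checkConfusion(cm)
  average <- match.arg(average, c("macro", "weighted"))
  if (is.null(perClass)) perClass <- perClassMetrics(cm)
  total <- sum(cm)
  acc <- if (total > 0) sum(diag(cm)) / total else 0
  wts <- if (average == "macro") {
    rep(1 / nrow(cm), nrow(cm))
  } else {
    rowSums(cm) / total
  }
  data.frame(
    accuracy = acc,
    precision = sum(wts * perClass$precision),
    recall = sum(wts * perClass$recall),
    f1 = sum(wts * perClass$f1),
    average = average,
    stringsAsFactors = FALSE
  )
}

#' Full metrics report
#'
#' @inheritParams computeConfusion
#' @param probabilities optional `N x n` probability matrix (columns
#'   ordered as `classLabels`); when supplied a macro one-vs-rest AUC is
#'   included.
#' @param average aggregation convention for precision/recall/F1.
#' @return a list with `confusion`, `perClass`, `aggregate` and `auc`
#'   (NA when probabilities are not supplied).
#' @export
metricsReport <- function(true, predicted, classLabels = NULL,
                          probabilities = NULL, average = "macro") {
  cm <- computeConfusion(true, predicted, classLabels)
  pc <- perClassMetrics(cm)
  agg <- aggregateMetrics(cm, pc, average)
  auc <- NA_real_
  if (!is.null(probabilities)) {
    auc <- multiclassAuc(true, probabilities, rownames(cm))
  }
  list(confusion = cm, perClass = pc, aggregate = agg, auc = auc)
}

.binaryAucTrapezoid <- function(scores, positive) {
  # ROC by sweeping thresholds over the unique scores (predict positive at
  # score >= t), trapezoidal area; equals the Mann-Whitney statistic with
  # ties counted 1/2.
  npos <- sum(positive)
  nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(scores[positive] >= t) / npos,
                     numeric(1)))
  fpr <- c(0, vapply(th, function(t) sum(scores[!positive] >= t) / nneg,
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Macro one-vs-rest multiclass AUC
#'
#' For each class, the class-probability column scores a binary
#' positive-vs-rest problem; the ROC area is computed by trapezoidal
#' integration over the unique score thresholds, and areas are averaged
#' without weights. Classes absent from `true` are excluded with a
#' warning.
#'
#' @param true true label vector.
#' @param probabilities `N x n` matrix of class probabilities; each row
#'   must be a valid probability vector.
#' @param classLabels class names ordering the probability columns;
#'   defaults to `colnames(probabilities)`.
#' @return the macro-averaged area in `[0, 1]`.
#' @export
multiclassAuc <- function(true, probabilities, classLabels = NULL) {
  probabilities <- as.matrix(probabilities)
  if (is.null(classLabels)) classLabels <- colnames(probabilities)
  if (is.null(classLabels)) {
    stop("classLabels required when probabilities has no column names")
  }
  if (length(true) != nrow(probabilities)) {
    stop("label count does not match probability rows")
  }
  if (any(probabilities < -1e-9) ||
      any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    stop("probability rows must be nonnegative and sum to 1")
  }
  true <- as.character(true)
  aucs <- numeric(0)
  missing <- character(0)
  for (i in seq_along(classLabels)) {
    pos <- true == classLabels[i]
    if (!any(pos)) {
      missing <- c(missing, classLabels[i])
      next
    }
    a <- .binaryAucTrapezoid(probabilities[, i], pos)
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  if (length(missing)) {
    warning("class(es) absent from true labels excluded from macro AUC: ",
            paste(missing, collapse = ", "))
  }
  mean(aucs)
}

#' Write a confusion matrix / metrics report to disk
#'
#' `writeConfusionCsv` writes the count table with class names as header
#' row and column. `writeMetricsCsv` writes one row per class plus an
#' aggregate row; `writeMetricsJson` serializes the full report.
#'
#' @param cm confusion matrix.
#' @param report a [metricsReport()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeConfusionCsv <- function(cm, path) {
  df <- as.data.frame.matrix(cm)
  df <- cbind(true = rownames(cm), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConfusionCsv
#' @export
writeMetricsCsv <- function(report, path) {
  pc <- report$perClass[, c("class", "accuracy", "precision", "recall",
                            "f1", "degenerate")]
  agg <- data.frame(
    class = sprintf("<%s>", report$aggregate$average),
    accuracy = report$aggregate$accuracy,
    precision = report$aggregate$precision,
    recall = report$aggregate$recall,
    f1 = report$aggregate$f1,
    degenerate = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(pc, agg), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConfusionCsv
#' @export
writeMetricsJson <- function(report, path) {
  out <- list(
    orientation = "rows = true, columns = predicted",
    confusion = unclass(report$confusion),
    classLabels = rownames(report$confusion),
    perClass = report$perClass,
    aggregate = report$aggregate,
    auc = report$auc
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
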