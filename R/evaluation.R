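#' @include model.R
NULL

#' One-vs-rest confusion counts
#'
#' For each class in `classes`, counts true positives, false positives,
#' false negatives and true negatives of the predicted labels against the
#' gold labels.
#'
#' @param gold,predicted Equal-length label vectors.
#' @param classes Ordered class vocabulary.
#' @return data.frame with one row per class and columns `class`, `TP`,
#'   `FP`, `FN`, `TN`.
#' @examples
#' confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
confusionCounts <- function(gold, predicted, classes) {
  gold <- as.character(gold); predicted <- as.character(predicted)
  if (length(gold) != length(predicted))
    stop("value error: gold and predicted lengths differ", call. = FALSE)
  bad <- setdiff(c(gold, predicted), classes)
  if (length(bad))
    stop(sprintf("value error: label '%s' not in class list", bad[1L]),
         call. = FALSE)
  out <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L, TN = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    cls <- classes[i]
    out$TP[i] <- sum(gold == cls & predicted == cls)
    out$FP[i] <- sum(gold != cls & predicted == cls)
    out$FN[i] <- sum(gold == cls & predicted != cls)
    out$TN[i] <- sum(gold != cls & predicted != cls)
  }
  out
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`, with
#' the zero-division conventions P = 0 when TP + FP = 0, R = 0 when
#' TP + FN = 0, and F1 = 0 when P = R = 0.
#'
#' @param counts Output of [confusionCounts()] (or any data.frame with
#'   `TP`, `FP`, `FN` columns).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
precisionRecallF1 <- function(counts) {
  P <- ifelse(counts$TP + counts$FP == 0, 0,
              counts$TP / (counts$TP + counts$FP))
  R <- ifelse(counts$TP + counts$FN == 0, 0,
              counts$TP / (counts$TP + counts$FN))
  F1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  data.frame(class = counts$class, precision = P, recall = R, f1 = F1,
             stringsAsFactors = FALSE)
}

#' Macro-average of per-class metrics
#'
#' Unweighted arithmetic mean of precision, recall and F1 over classes.
#'
#' @param per_class Output of [precisionRecallF1()] (nonempty).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
macroAverage <- function(per_class) {
  if (!nrow(per_class)) stop("value error: no classes to average",
                             call. = FALSE)
  c(precision = mean(per_class$precision), recall = mean(per_class$recall),
    f1 = mean(per_class$f1))
}

## Per-task metrics over pooled gold/predicted labels; classes absent from
## the gold labels are excluded from the macro average so small folds do
## not contribute undefined rows.
.taskMetrics <- function(gold, predicted, classes) {
  counts <- confusionCounts(gold, predicted, classes)
  per_class <- precisionRecallF1(counts)
  present <- counts$class %in% unique(as.character(gold))
  list(counts = counts, per_class = per_class,
       macro = macroAverage(per_class[present, , drop = FALSE]))
}

#' Compute a metrics report for predictions against gold labels
#'
#' Per-task one-vs-rest confusion counts, per-class precision/recall/F1,
#' per-task macro averages (over classes present in the gold labels), the
#' overall macro across the three tasks, and per-task macro AUC from the
#' one-vs-rest ROC curves of the softmax probabilities.
#'
#' @param pred A [SemanticPredictions-class].
#' @param gold data.frame with `location`, `texture`, `margin` columns.
#' @return A list of class `"MetricsReport"`: `per_task` (counts,
#'   per-class metrics, macro, macro_auc), `overall` macro, `n_evaluated`.
#' @export
metricsReport <- function(pred, gold) {
  stopifnot(is(pred, "SemanticPredictions"))
  per_task <- list()
  for (task in .TASKS) {
    lv <- .taskLevels(task)
    tm <- .taskMetrics(as.character(gold[[task]]),
                       as.character(predictedLabels(pred)[[task]]), lv)
    P <- taskProbabilities(pred, task)
    g <- as.character(gold[[task]])
    aucs <- vapply(lv, function(cls) {
      y <- as.integer(g == cls)
      if (length(unique(y)) < 2L) return(NA_real_)
      rocCurve(P[, cls], y)$auc
    }, numeric(1L))
    tm$class_auc <- aucs
    tm$macro_auc <- mean(aucs, na.rm = TRUE)
    per_task[[task]] <- tm
  }
  overall <- rowMeans(vapply(per_task, `[[`, numeric(3L), "macro"))
  out <- list(per_task = per_task, overall = overall,
              n_evaluated = nrow(gold))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport over %d record(s)\n", x$n_evaluated))
  for (task in names(x$per_task)) {
    m <- x$per_task[[task]]$macro
    cat(sprintf("  %-8s macro P/R/F1 = %.4f / %.4f / %.4f  (macro AUC %.4f)\n",
                task, m["precision"], m["recall"], m["f1"],
                x$per_task[[task]]$macro_auc))
  }
  cat(sprintf("  overall  macro P/R/F1 = %.4f / %.4f / %.4f\n",
              x$overall["precision"], x$overall["recall"], x$overall["f1"]))
  invisible(x)
}

#' ROC curve and trapezoidal AUC for binary gold labels
#'
#' Sweeps thresholds over the distinct prediction scores (ties grouped),
#' yielding monotone (FPR, TPR) points from (0, 0) to (1, 1); the AUC is
#' the trapezoid-rule area, equivalent to the Mann-Whitney U statistic
#' normalized by the number of positive-negative pairs with half credit
#' for ties.
#'
#' @param scores Numeric prediction scores (higher means more positive).
#' @param gold Binary 0/1 gold labels, at least one of each.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocCurve <- function(scores, gold) {
  gold <- as.integer(gold)
  if (length(scores) != length(gold))
    stop("value error: scores and gold lengths differ", call. = FALSE)
  if (!all(gold %in% c(0L, 1L)))
    stop("value error: gold must be binary 0/1", call. = FALSE)
  n_pos <- sum(gold == 1L); n_neg <- sum(gold == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("value error: need at least one positive and one negative",
         call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & gold == 1L), 0) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & gold == 0L), 0) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Leave-one-out cross-validation
#'
#' Runs one train/test fold per record: fold `i` trains on every record
#' except `i` (with a deterministic per-fold seed derived from the config
#' seed) and predicts the held-out record. The pooled held-out predictions
#' are scored with one confusion matrix per task across all folds.
#'
#' @param cohort A fully labeled [NoduleCohort-class] with at least 2
#'   records.
#' @param config A [modelConfig()].
#' @param progress Print a note every `progress` folds (0 = silent).
#' @return List with `predictions` (pooled [SemanticPredictions-class]),
#'   `metrics` (a `MetricsReport`), and `n_folds`.
#' @export
loocv <- function(cohort, config = modelConfig(), progress = 0L) {
  stopifnot(is(cohort, "NoduleCohort"))
  n <- ncol(cohort)
  if (n < 2L) stop("value error: LOOCV needs at least 2 records",
                   call. = FALSE)
  if (!all(.isLabeled(cohort)))
    stop("value error: LOOCV requires gold labels on every record",
         call. = FALSE)
  set.seed(config$seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, n)
  probs <- lapply(.TASKS, function(task)
    matrix(NA_real_, n, length(.taskLevels(task)),
           dimnames = list(colnames(cohort), .taskLevels(task))))
  names(probs) <- .TASKS
  for (i in seq_len(n)) {
    fold_cfg <- config
    fold_cfg$seed <- fold_seeds[i]
    model <- initModel(fold_cfg, cohortRegistry(cohort))
    model <- trainModel(model, cohort[, -i], fold_cfg)
    p <- predict(model, cohort[, i])
    for (task in .TASKS) probs[[task]][i, ] <- taskProbabilities(p, task)
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("loocv: fold %d/%d", i, n))
  }
  pooled <- .newPredictions(probs, colnames(cohort))
  list(predictions = pooled,
       metrics = metricsReport(pooled, semanticLabels(cohort)),
       n_folds = n)
}
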