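#' Confusion-matrix cell counts for binary predictions
#'
#' Counts TP, TN, FP, FN with class 1 as the positive class (here: the
#' diseased / diabetic class).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_counts: length mismatch")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("confusion_counts: labels must be 0/1")
  }
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Precision = TP/(TP+FP), \quad Recall = TP/(TP+FN)}
#' \deqn{F1 = 2 \cdot Precision \cdot Recall / (Precision + Recall)}
#' Degenerate denominators follow the usual convention: precision is 0 when
#' nothing is predicted positive, recall is 0 when there are no positives,
#' F1 is 0 when precision + recall = 0.
#'
#' @param counts A list with `TP`, `TN`, `FP`, `FN` (as from
#'   [confusion_counts()]), or a 0/1 truth vector when `y_pred` is given.
#' @param y_pred Optional predictions; if supplied, `counts` is treated as
#'   `y_true` and the confusion counts are computed first.
#' @return Object of class `"metrics_report"`: list with `accuracy`,
#'   `precision`, `recall`, `f1` and the `counts`.
#' @export
metrics <- function(counts, y_pred = NULL) {
  if (!is.null(y_pred)) counts <- confusion_counts(counts, y_pred)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("metrics: no samples")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(accuracy = (tp + tn) / total, precision = precision,
                 recall = recall, f1 = f1, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy %.*f  precision %.*f  recall %.*f  F1 %.*f\n",
              digits, x$accuracy, digits, x$precision, digits, x$recall,
              digits, x$f1))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold holds both classes whenever counts permit.
stratified_folds <- function(y, folds, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold_id <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Fits the classifier on each training fold and evaluates accuracy,
#' precision, recall and F1 on the held-out fold. Folds are stratified so
#' each contains both classes; the per-metric summary reports the mean and
#' the population (n-denominator) standard deviation over folds.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds, default 5; must not exceed the minority
#'   class count.
#' @return Object of class `"cv_report"`: `per_fold` (data frame of fold
#'   metrics), `mean`, `sd` (named numeric vectors), `folds`, `seed`.
#' @export
cross_validate <- function(classifier, X, y, folds = 5,
                           class_weight = "balanced", params = list(),
                           seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(folds >= 2)
  n_min <- min(table(y))
  if (n_min < folds) {
    stop("cross_validate: minority class count (", n_min,
         ") smaller than fold count (", folds, ")")
  }
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "cv"))
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- train_classifier(classifier, X[tr, , drop = FALSE], y[tr],
                              class_weight = class_weight, params = params,
                              seed = derive_seed(seed, "model") + f)
    pred <- predict_class(model, X[!tr, , drop = FALSE])
    m <- metrics(confusion_counts(y[!tr], pred))
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1)
  })
  per_fold <- do.call(rbind, per_fold)
  mu <- colMeans(per_fold)
  sdv <- apply(per_fold, 2, function(v) sqrt(mean((v - mean(v))^2)))
  structure(list(per_fold = as.data.frame(per_fold), mean = mu, sd = sdv,
                 folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(x$folds, "-fold cross-validation (stratified)\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  invisible(x)
}

#' Paired two-sided t-test on per-fold scores
#'
#' Standard paired t-test on the differences `scores_a - scores_b`. When
#' every difference is exactly zero the test statistic is undefined and the
#' comparison is a tie: `t = NA`, `p = 1`. When the differences are
#' constant but nonzero the statistic diverges; `t` is reported as signed
#' infinity with `p = 0` and `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2),
#'   e.g. per-fold F1 of two models on the same folds.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired_ttest: length mismatch")
  }
  stopifnot(length(scores_a) >= 2)
  d <- scores_a - scores_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = NA_real_, p = 1, df = n - 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Normalize confusion counts to proportions
#'
#' Divides each cell by the total so that TP, TN, FP, FN become fractions
#' in \[0, 1\] summing to 1; useful for reporting alongside the raw counts.
#'
#' @param counts Confusion counts list.
#' @return Named numeric vector of proportions.
#' @export
normalize_confusion <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("normalize_confusion: no samples")
  c(TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN) / total
}
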