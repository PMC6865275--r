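# Evaluation: one-vs-rest metrics with bootstrap confidence intervals,
# the McNemar-Bowker paired symmetry test, confusion matrices and
# one-vs-rest ROC curves.

#' 4-class confusion matrix
#'
#' Rows are the reference standard, columns the prediction.
#'
#' @param truth,pred vectors of class labels
#' @param classes class levels (risk order)
#' @return 4 x 4 integer matrix
#' @export
confusion_matrix <- function(truth, pred, classes = class_order()) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the class set")
  as.matrix(table(reference = truth, prediction = pred))
}

#' One-vs-rest metrics for a class
#'
#' Collapses the confusion matrix to class-vs-rest and reports accuracy,
#' recall, precision, specificity and F1.  A metric with a zero denominator
#' is returned as 0 and flagged in the `undefined` attribute, so that mean
#' rows stay computable.
#'
#' @param cm confusion matrix from [confusion_matrix()]
#' @param class class name or row index
#' @return named numeric vector (accuracy, recall, precision, specificity,
#'   f1) with attribute `undefined` naming any zero-denominator metrics
#' @export
one_vs_rest_metrics <- function(cm, class) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  if (is.character(class)) class <- match(class, rownames(cm))
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      return(0)
    }
    num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  specificity <- safe(tn, tn + fp, "specificity")
  accuracy <- (tp + tn) / sum(cm)
  f1 <- if (precision + recall == 0) {
    undef <- c(undef, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(c(accuracy = accuracy, recall = recall, precision = precision,
              specificity = specificity, f1 = f1),
            undefined = undef)
}

#' Mean metrics row: unweighted average over classes
#'
#' @param per_class matrix or data frame, one row per class, metric columns
#' @return named numeric vector of column means
#' @export
mean_metrics <- function(per_class) {
  colMeans(as.matrix(per_class))
}

# Named metric functions operating on (truth, pred) label vectors,
# one-vs-rest for `class`.
metric_fun <- function(metric, class, classes = class_order()) {
  force(metric); force(class); force(classes)
  function(truth, pred) {
    cm <- confusion_matrix(truth, pred, classes)
    unname(one_vs_rest_metrics(cm, class)[metric])
  }
}

#' Bootstrap percentile confidence interval for a paired metric
#'
#' Resamples (label, prediction) pairs with replacement `B` times and
#' returns the plug-in point estimate with the percentile interval.
#' Deterministic given the seed.  Degenerate resamples (a class absent)
#' are handled by the metric's zero-denominator rule.
#'
#' @param truth,pred label vectors
#' @param metric a function(truth, pred) -> scalar, or a metric name
#'   ("accuracy", "recall", ...) combined with `class`
#' @param class class for named one-vs-rest metrics
#' @param B bootstrap replicates
#' @param level confidence level
#' @param seed RNG seed
#' @return named numeric c(point, lower, upper)
#' @export
bootstrap_ci <- function(truth, pred, metric = "accuracy", class = NULL,
                         B = 2000, level = 0.95, seed = 1) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2, B >= 100)
  if (is.character(metric)) {
    stopifnot(!is.null(class))
    metric <- metric_fun(metric, class)
  }
  set.seed(seed)
  n <- length(truth)
  point <- metric(truth, pred)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    stat[b] <- metric(truth[idx], pred[idx])
  }
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  c(point = point, lower = qs[1], upper = qs[2])
}

#' Full metrics report with bootstrap confidence intervals
#'
#' Per-class one-vs-rest accuracy, recall, precision, specificity and F1
#' with percentile bootstrap intervals, plus the unweighted mean row over
#' the four classes (also bootstrapped).
#'
#' @param truth,pred label vectors
#' @param classes class levels
#' @param B bootstrap replicates
#' @param level confidence level
#' @param seed RNG seed
#' @return data frame of class `metrics_report`: columns class, metric,
#'   point, lower, upper
#' @export
metrics_report <- function(truth, pred, classes = class_order(), B = 2000,
                           level = 0.95, seed = 1) {
  metrics <- c("accuracy", "recall", "precision", "specificity", "f1")
  rows <- list()
  for (cl in classes) {
    for (m in metrics) {
      ci <- bootstrap_ci(truth, pred, metric = m, class = cl, B = B,
                         level = level, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(class = cl, metric = m,
                                             point = ci["point"],
                                             lower = ci["lower"],
                                             upper = ci["upper"])
    }
  }
  mean_fun <- function(m) {
    function(truth, pred) {
      cm <- confusion_matrix(truth, pred, classes)
      mean(vapply(classes,
                  function(cl) unname(one_vs_rest_metrics(cm, cl)[m]), 0))
    }
  }
  for (m in metrics) {
    ci <- bootstrap_ci(truth, pred, metric = mean_fun(m), B = B,
                       level = level, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(class = "mean", metric = m,
                                           point = ci["point"],
                                           lower = ci["lower"],
                                           upper = ci["upper"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' McNemar-Bowker symmetry test for two paired classifiers
#'
#' Builds the K x K table `n[i, j]` counting samples classifier A assigns
#' to class i and classifier B to class j, and tests symmetry:
#' `X2 = sum over i < j with n_ij + n_ji > 0 of
#' (n_ij - n_ji)^2 / (n_ij + n_ji)`, with one degree of freedom per
#' included pair, against the upper tail of the chi-square distribution.
#' With all off-diagonal sums zero the statistic is 0 and p = 1.
#'
#' @param y_true reference labels (defines the pairing; categories come
#'   from the union of both prediction vectors and `classes`)
#' @param pred_a,pred_b predictions of the two classifiers on the same
#'   samples
#' @param classes category levels
#' @return list(statistic, df, p_value, table)
#' @export
mcnemar_bowker <- function(y_true, pred_a, pred_b, classes = NULL) {
  stopifnot(length(pred_a) == length(pred_b))
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(pred_a), as.character(pred_b))))
  }
  a <- factor(as.character(pred_a), levels = classes)
  b <- factor(as.character(pred_b), levels = classes)
  tab <- table(a, b)
  K <- length(classes)
  stat <- 0
  df <- 0L
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      s <- tab[i, j] + tab[j, i]
      if (s > 0) {
        stat <- stat + (tab[i, j] - tab[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, table = tab)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps the decision threshold on the class's predicted probability and
#' reports (false-positive rate, true-positive rate) points plus the
#' trapezoid-rule AUC; tied scores are handled by rank averaging, so the
#' AUC equals the normalized Mann-Whitney U statistic.
#'
#' @param truth label vector
#' @param probs matrix/data frame of class probabilities (columns named by
#'   class) or a numeric vector of scores for `class`
#' @param class the positive class
#' @return list(curve = data.frame(threshold, fpr, tpr), auc); `auc` is NA
#'   with a warning when only one class is present
#' @export
roc_auc <- function(truth, probs, class) {
  score <- if (is.numeric(probs) && is.null(dim(probs))) probs else {
    as.matrix(probs)[, class]
  }
  pos <- as.character(truth) == class
  if (all(pos) || !any(pos)) {
    warning("AUC undefined: only one class present")
    return(list(curve = NULL, auc = NA_real_))
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(score[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[!pos] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
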