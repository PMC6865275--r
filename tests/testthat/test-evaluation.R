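# One-vs-rest metrics, bootstrap intervals, McNemar-Bowker, ROC/AUC.

toy_cm <- function() {
  # collapsing class 1 vs rest gives TP=3, FN=2, FP=1, TN=4
  cm <- matrix(0L, 4, 4, dimnames = list(class_order(), class_order()))
  cm[1, 1] <- 3L; cm[1, 2] <- 2L; cm[2, 1] <- 1L; cm[2, 2] <- 4L
  cm
}

test_that("one-vs-rest metrics on the toy matrix are exact", {
  m <- one_vs_rest_metrics(toy_cm(), 1)
  expect_equal(unname(m["recall"]), 0.6, tolerance = 1e-9)
  expect_equal(unname(m["precision"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(m["accuracy"]), 0.7, tolerance = 1e-9)
  expect_equal(unname(m["specificity"]), 0.8, tolerance = 1e-9)
  expect_equal(unname(m["f1"]), 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-9)
})

test_that("perfect and degenerate confusion matrices", {
  perf <- diag(c(5L, 3L, 2L, 4L))
  dimnames(perf) <- list(class_order(), class_order())
  for (cl in class_order()) {
    expect_equal(as.numeric(one_vs_rest_metrics(perf, cl)), rep(1, 5))
  }
  # class absent from reference and predictions: recall undefined -> 0
  m <- one_vs_rest_metrics(perf - diag(c(0L, 0L, 2L, 0L)), 3)
  expect_equal(unname(m["recall"]), 0)
  expect_true("recall" %in% attr(m, "undefined"))
})

test_that("metrics agree with direct counting over label vectors", {
  set.seed(71)
  for (rep in 1:5) {
    truth <- sample(class_order(), 60, replace = TRUE)
    pred <- sample(class_order(), 60, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    expect_equal(sum(cm), 60)
    for (cl in class_order()) {
      m <- one_vs_rest_metrics(cm, cl)
      pos <- truth == cl
      expect_equal(unname(m["recall"]),
                   if (any(pos)) mean(pred[pos] == cl) else 0)
      expect_equal(unname(m["specificity"]), mean(pred[!pos] != cl))
    }
  }
})

test_that("the mean row is the unweighted average over classes", {
  expect_equal(unname(mean_metrics(cbind(accuracy =
    c(0.70, 0.85, 0.89, 0.88)))), 0.83, tolerance = 1e-9)
  expect_equal(unname(mean_metrics(cbind(x = c(0, 1, 1, 1)))), 0.75)
  same <- matrix(0.6, 4, 5)
  expect_equal(unname(mean_metrics(same)), rep(0.6, 5))
})

test_that("bootstrap intervals: point estimate, determinism, shrinkage", {
  truth <- rep(class_order(), each = 10)
  ci <- bootstrap_ci(truth, truth, metric = "accuracy", class = "normal",
                     B = 200, seed = 2)
  expect_equal(unname(ci), c(1, 1, 1))
  set.seed(72)
  pred <- ifelse(runif(40) < 0.8, truth, sample(class_order(), 40, TRUE))
  ci1 <- bootstrap_ci(truth, pred, metric = "accuracy", class = "normal",
                      B = 500, seed = 7)
  ci2 <- bootstrap_ci(truth, pred, metric = "accuracy", class = "normal",
                      B = 500, seed = 7)
  expect_identical(ci1, ci2)
  # point estimate equals the plug-in metric
  expect_equal(unname(ci1["point"]),
               unname(one_vs_rest_metrics(confusion_matrix(truth, pred),
                                          "normal")["accuracy"]))
  # interval width shrinks with n (same 0.8-accuracy generating process)
  make <- function(n, seed) {
    set.seed(seed)
    tr <- sample(class_order(), n, replace = TRUE)
    pr <- ifelse(runif(n) < 0.8, tr, sample(class_order(), n, TRUE))
    ci <- bootstrap_ci(tr, pr, metric = "accuracy", class = "normal",
                       B = 400, seed = 1)
    unname(ci["upper"] - ci["lower"])
  }
  expect_lt(make(1000, 5), make(100, 5))
})

test_that("metrics_report covers classes, mean row, and CI ordering", {
  set.seed(73)
  truth <- sample(class_order(), 50, replace = TRUE)
  pred <- ifelse(runif(50) < 0.7, truth, sample(class_order(), 50, TRUE))
  rep <- metrics_report(truth, pred, B = 200, seed = 1)
  expect_equal(nrow(rep), 25L)         # (4 classes + mean) x 5 metrics
  expect_true(all(rep$lower <= rep$point + 1e-12))
  expect_true(all(rep$point <= rep$upper + 1e-12))
  expect_true(all(rep$point >= 0 & rep$point <= 1))
})

test_that("McNemar-Bowker statistic, df and p-value", {
  # perfectly symmetric disagreement
  a <- c(rep("normal", 5), rep("adenocarcinoma", 5))
  b <- c(rep("adenocarcinoma", 5), rep("normal", 5))
  r <- mcnemar_bowker(NULL, a, b)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # 2-class table with n_01 = 6, n_10 = 2
  a2 <- c(rep("x", 6), rep("y", 2), rep("x", 4))
  b2 <- c(rep("y", 6), rep("x", 2), rep("x", 4))
  r2 <- mcnemar_bowker(NULL, a2, b2)
  expect_equal(r2$statistic, 2.0, tolerance = 1e-12)
  expect_equal(r2$df, 1L)
  expect_equal(r2$p_value, pchisq(2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(r2$p_value, 4), 0.1573)
  # identical predictions: all off-diagonals empty
  r3 <- mcnemar_bowker(NULL, a, a)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$df, 0L)
  expect_equal(r3$p_value, 1)
})

test_that("McNemar-Bowker is invariant to category relabelling", {
  set.seed(74)
  a <- sample(class_order(), 80, replace = TRUE)
  b <- sample(class_order(), 80, replace = TRUE)
  r1 <- mcnemar_bowker(NULL, a, b)
  perm <- rev(class_order())
  r2 <- mcnemar_bowker(NULL, a, b, classes = perm)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$df, r2$df)
})

test_that("ROC/AUC: separation, chance level, and a library cross-check", {
  # perfectly separating scores
  r <- roc_auc(c("a", "a", "n", "n"), c(0.9, 0.8, 0.4, 0.3), "a")
  expect_equal(r$auc, 1.0)
  # chance level at large n
  set.seed(75)
  truth <- sample(c("a", "n"), 4000, replace = TRUE)
  score <- runif(4000)
  expect_equal(roc_auc(truth, score, "a")$auc, 0.5, tolerance = 0.05)
  # single-class labels are flagged
  expect_warning(und <- roc_auc(rep("a", 5), runif(5), "a"), "undefined")
  expect_true(is.na(und$auc))
  skip_if_not_installed("pROC")
  set.seed(76)
  tr <- sample(c("a", "n"), 80, replace = TRUE)
  sc <- runif(80) + 0.3 * (tr == "a")
  ours <- roc_auc(tr, sc, "a")$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(tr == "a", sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})
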