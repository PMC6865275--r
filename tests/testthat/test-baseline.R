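# Sliding-window baseline: crop set, window inference, heuristics.

baseline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(16, width = 96, height = 72, seed = 81,
                                 lesion_frac = c(0.3, 0.45))
    }
    cache
  }
})

test_that("crop sets sample inside boxes and skip undersized boxes", {
  ds <- baseline_fixture()
  expect_warning(
    cs <- make_crop_set(ds$manifest, ds$boxes, crop_px = 16, per_box = 3,
                        per_normal = 2, seed = 1),
    regexp = NA)                        # lesions >= 21 px, nothing skipped
  expect_equal(dim(cs$crops)[1:3], c(16L, 16L, 3L))
  # every lesion crop's center lies inside its source box
  lesion_rows <- cs$centers[cs$centers$class != "normal", ]
  for (r in seq_len(nrow(lesion_rows))) {
    bx <- ds$boxes[ds$boxes$tissue_id == lesion_rows$tissue_id[r] &
                   ds$boxes$class == lesion_rows$class[r], ]
    inside <- any(lesion_rows$x[r] >= bx$x_min & lesion_rows$x[r] <= bx$x_max &
                  lesion_rows$y[r] >= bx$y_min & lesion_rows$y[r] <= bx$y_max)
    expect_true(inside)
  }
  # determinism
  cs2 <- make_crop_set(ds$manifest, ds$boxes, crop_px = 16, per_box = 3,
                       per_normal = 2, seed = 1)
  expect_identical(cs$crops, cs2$crops)
  # oversized crop demand skips all boxes
  expect_warning(
    expect_error(make_crop_set(ds$manifest[ds$manifest$label != "normal", ],
                               ds$boxes, crop_px = 64, seed = 1),
                 "no usable crops"),
    "smaller than")
  # and missing boxes fail loudly
  expect_error(make_crop_set(ds$manifest, NULL, crop_px = 16),
               "requires lesion bounding-box annotations")
})

test_that("crop classifier learns separable crops", {
  ds <- baseline_fixture()
  cs <- make_crop_set(ds$manifest, ds$boxes, crop_px = 16, per_box = 3,
                      per_normal = 3, seed = 2)
  clf <- train_crop_classifier(cs, epochs = 8, k = 8, batch_size = 16,
                               seed = 2)
  expect_lt(clf$loss_trace[8], clf$loss_trace[1])
  p <- predict_crops(clf, cs$crops[, , , 1:5])
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
})

test_that("window tiling arithmetic and neighbour independence", {
  ds <- baseline_fixture()
  cs <- make_crop_set(ds$manifest, ds$boxes, crop_px = 16, seed = 3)
  clf <- train_crop_classifier(cs, epochs = 2, k = 8, seed = 3)
  tissue <- array(0.5, dim = c(32, 32, 3))
  wg <- classify_windows(tissue, clf, window_px = 16, stride = 16)
  expect_equal(nrow(wg$probs), 4L)                  # 2 x 2 windows
  wg2 <- classify_windows(tissue, clf, window_px = 16, stride = 8)
  expect_gte(nrow(wg2$probs), nrow(wg$probs))
  # tissue smaller than the window: one padded window
  small <- array(0.5, dim = c(10, 10, 3))
  expect_equal(nrow(classify_windows(small, clf, window_px = 16)$probs), 1L)
  # windows are classified independently: perturbing one region leaves
  # the other windows' probabilities untouched
  t2 <- tissue
  t2[1:16, 1:16, ] <- 0.1
  wgp <- classify_windows(t2, clf, window_px = 16, stride = 16)
  expect_equal(wg$probs[2:4, ], wgp$probs[2:4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(wg$probs[1, ], wgp$probs[1, ])))
})

test_that("heuristic aggregation follows the count-threshold priority rule", {
  mk <- function(p) {
    structure(list(probs = p, coords = NULL), class = "window_grid")
  }
  classes <- class_order()
  # all windows confidently normal
  pn <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 5), ncol = 4, byrow = TRUE,
               dimnames = list(NULL, classes))
  expect_equal(aggregate_windows(mk(pn)), "normal")
  # one adenocarcinoma-confident window beats a normal majority
  pa <- pn
  pa[3, ] <- c(0.05, 0.05, 0.05, 0.85)
  hc <- heuristic_config()
  expect_equal(aggregate_windows(mk(pa), hc), "adenocarcinoma")
  # raising the threshold above the window's confidence flips it back
  hc2 <- heuristic_config(thresholds = c("BE-no-dysplasia" = 0.5,
                                         "BE-with-dysplasia" = 0.5,
                                         "adenocarcinoma" = 0.9))
  expect_equal(aggregate_windows(mk(pa), hc2), "normal")
  # threshold monotonicity of confident-window counts
  set.seed(84)
  pr <- matrix(runif(40), ncol = 4, dimnames = list(NULL, classes))
  pr <- pr / rowSums(pr)
  cnt <- function(th) sum(pr[, "adenocarcinoma"] > th)
  ths <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(ths, cnt, 0)) <= 0))
  # permutation invariance over windows
  expect_equal(aggregate_windows(mk(pa[sample(nrow(pa)), ]), hc),
               aggregate_windows(mk(pa), hc))
})

test_that("the heuristic grid search is exhaustive and deterministic", {
  set.seed(85)
  classes <- class_order()
  grids <- lapply(1:10, function(i) {
    p <- matrix(runif(24), ncol = 4, dimnames = list(NULL, classes))
    structure(list(probs = p / rowSums(p), coords = NULL),
              class = "window_grid")
  })
  labels <- sample(classes, 10, replace = TRUE)
  gs <- grid_search_heuristic(grids, labels, thr_grid = c(0.3, 0.5),
                              count_grid = c(1, 2))
  expect_s3_class(gs$config, "heuristic_config")
  expect_equal(gs$searched, (2 * 2)^3)
  # no other combination scores higher
  for (th in c(0.3, 0.5)) {
    hc <- heuristic_config(
      thresholds = setNames(rep(th, 3), setdiff(classes, "normal")),
      min_counts = setNames(rep(1, 3), setdiff(classes, "normal")))
    preds <- vapply(grids, aggregate_windows, "", heuristic = hc)
    cm <- confusion_matrix(labels, preds)
    sc <- mean(vapply(classes,
                      function(cl) unname(one_vs_rest_metrics(cm, cl)["f1"]),
                      0))
    expect_lte(sc, gs$score + 1e-12)
  }
  gs2 <- grid_search_heuristic(grids, labels, thr_grid = c(0.3, 0.5),
                               count_grid = c(1, 2))
  expect_identical(gs$config, gs2$config)
  # singleton grids return that configuration
  gs1 <- grid_search_heuristic(grids, labels, thr_grid = 0.5, count_grid = 1)
  expect_true(all(gs1$config$thresholds == 0.5))
  expect_true(all(gs1$config$min_counts == 1))
})

test_that("the baseline trains end-to-end and predicts tissue classes", {
  ds <- baseline_fixture()
  fit <- baseline_fit(ds$manifest, ds$boxes, crop_px = 16, epochs = 6,
                      k = 8, seed = 9)
  expect_s3_class(fit, "wsi_baseline")
  expect_output(print(fit), "Sliding-window baseline")
  pred <- predict(fit, ds$manifest)
  expect_s3_class(pred, "factor")
  expect_length(pred, nrow(ds$manifest))
  expect_error(baseline_fit(ds$manifest, NULL),
               "requires lesion bounding-box annotations")
})
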