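# Prediction, attention-map rendering, enrichment and head selection.

make_tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(12, width = 96, height = 72, seed = 61)
      cfg <- train_config(total_epochs = 2, val_fraction = 0.2, seed = 6)
      cache <<- list(fit = wsi_attention(ds$manifest, backbone = "cnn",
                                         k = 8, cell_px = 24, out_px = 16,
                                         n_filters = 4, config = cfg),
                     ds = ds)
    }
    cache
  }
})

test_that("prediction is deterministic and consistent with probabilities", {
  tf <- make_tiny_fit()
  img <- tf$ds$manifest$image[[1]]
  p1 <- predict(tf$fit, img, type = "prob")
  p2 <- predict(tf$fit, img, type = "prob")
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  cl <- predict(tf$fit, img, type = "class")
  expect_equal(as.character(cl), class_order()[which.max(as.matrix(p1))])
  at <- predict(tf$fit, img, type = "attention")[[1]]
  expect_equal(apply(at$alpha, 1, sum), rep(1, 4), tolerance = 1e-6)
})

test_that("attention rendering normalizes to max 1 and maps cells to blocks", {
  al <- matrix(c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1), 2, 3)
  ren <- render_attention(al, dims = c(40, 66), cell_px = 24)
  expect_equal(dim(ren), c(40L, 66L))
  expect_equal(max(ren), 1)
  # the peak cell is (2, 2): rows 25..40 (cropped), cols 25..48
  pk <- which(ren == 1, arr.ind = TRUE)
  expect_true(all(pk[, 1] >= 25 & pk[, 1] <= 48))
  expect_true(all(pk[, 2] >= 25 & pk[, 2] <= 48))
  # constant map renders all ones
  expect_true(all(render_attention(matrix(0.25, 2, 2), c(10, 10), 8) == 1))
  expect_warning(z <- render_attention(matrix(0, 2, 2), c(10, 10), 8),
                 "all-zero")
  expect_true(all(z == 0))
  # bilinear rendering keeps the argmax inside the peak cell
  renb <- render_attention(al, dims = c(48, 72), cell_px = 24,
                           method = "bilinear")
  pm <- which(renb == max(renb), arr.ind = TRUE)[1, ]
  expect_true(pm[1] >= 25 && pm[1] <= 48 && pm[2] >= 25 && pm[2] <= 48)
})

test_that("attention enrichment is the mass ratio over the area fraction", {
  uni <- matrix(1 / 12, 3, 4)
  mask <- matrix(FALSE, 3, 4); mask[1, 1] <- TRUE
  expect_equal(attention_enrichment(uni, mask), 1.0)
  expect_equal(attention_enrichment(uni, !logical(12) |> matrix(3, 4)), 1.0)
  conc <- matrix(0, 2, 2); conc[1, 1] <- 1
  m25 <- matrix(FALSE, 2, 2); m25[1, 1] <- TRUE
  expect_equal(attention_enrichment(conc, m25), 4.0)
  expect_error(attention_enrichment(uni, matrix(FALSE, 3, 4)), "empty")
})

test_that("grid lesion masks respect the overlap rule", {
  boxes <- data.frame(class = "adenocarcinoma", x_min = 0, y_min = 0,
                      x_max = 24, y_max = 24)
  m <- lesion_grid_mask(boxes, dims = c(48, 72), cell_px = 24)
  expect_equal(dim(m), c(2L, 3L))
  expect_identical(which(m), 1L)
  # a lesion much smaller than a cell still registers in its cell
  small <- data.frame(class = "adenocarcinoma", x_min = 30, y_min = 2,
                      x_max = 40, y_max = 12)
  m2 <- lesion_grid_mask(small, dims = c(48, 72), cell_px = 24)
  expect_true(m2[1, 2])
  expect_equal(sum(m2), 1L)
  # class filtering
  m3 <- lesion_grid_mask(boxes, dims = c(48, 72), cell_px = 24,
                         classes = "BE-no-dysplasia")
  expect_false(any(m3))
})

test_that("class-head selection follows classifier weight mass", {
  model <- tiny_model(k = 4, n_filters = 5, px = 8)
  model$clf$W[] <- 0
  model$clf$W[(2 * 4 + 1):(3 * 4), 4] <- c(1, -2, 0.5, 1)   # head 3 block
  expect_equal(select_class_head(model, "adenocarcinoma"), 3L)
  expect_equal(select_class_head(model, 4), 3L)
  # invariant under positive rescaling
  m2 <- model; m2$clf$W <- model$clf$W * 7.3
  expect_equal(select_class_head(m2, "adenocarcinoma"), 3L)
  set.seed(62)
  model$clf$W[] <- rnorm(length(model$clf$W))
  h <- select_class_head(model, "normal")
  expect_true(h >= 1 && h <= 5)
})

test_that("a saved model round-trips through JSON exactly", {
  tf <- make_tiny_fit()
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p), add = TRUE)
  save_model(tf$fit, p)
  re <- load_model(p)
  img <- tf$ds$manifest$image[[2]]
  expect_equal(predict(re, img, type = "prob"),
               predict(tf$fit, img, type = "prob"), tolerance = 1e-12)
  expect_equal(re$stats$mean, tf$fit$stats$mean)
})

test_that("attention_maps attaches enrichment for annotated tissues", {
  tf <- make_tiny_fit()
  eac <- which(tf$ds$manifest$label == "adenocarcinoma")
  skip_if(length(eac) == 0, "no adenocarcinoma tissue in fixture")
  am <- attention_maps(tf$fit, tf$ds$manifest[eac, , drop = FALSE],
                       boxes = tf$ds$boxes)
  expect_true(all(vapply(am, function(x) is.numeric(x$enrichment), TRUE)))
})
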