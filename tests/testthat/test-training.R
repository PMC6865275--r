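# Initialization scheme, learning-rate schedule, augmentation, training.

test_that("initialization follows the He/Glorot/unit-zero scheme", {
  model <- tiny_model(k = 6, n_filters = 4, px = 8, arch = "resnet")
  model <- initialize_weights(model, seed = 5)
  flat <- model_params(model)
  # batch norms exactly unit weight, zero bias
  for (nm in names(flat)) {
    leaf <- sub(".*\\.", "", nm)
    if (leaf == "gamma") expect_true(all(flat[[nm]] == 1))
    if (leaf == "beta") expect_true(all(flat[[nm]] == 0))
    if (leaf == "b") expect_true(all(flat[[nm]] == 0))
  }
  # conv variance ~ 2 / fan_in on a large tensor
  set.seed(6)
  W <- wsiattn:::init_msra(3, 3, 64, 64)
  expect_lt(abs(var(as.vector(W)) / (2 / (3 * 3 * 64)) - 1), 0.1)
  # fully connected variance ~ 2 / (fan_in + fan_out)
  Wfc <- wsiattn:::init_glorot(400, 300)
  expect_lt(abs(var(as.vector(Wfc)) / (2 / 700) - 1), 0.1)
  # determinism in the seed
  m1 <- initialize_weights(model, seed = 11)
  m2 <- initialize_weights(model, seed = 11)
  expect_identical(model_params(m1), model_params(m2))
})

test_that("learning-rate schedule matches its closed form", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-3)
  expect_equal(lr_schedule(1, cfg), 9.5e-4)
  expect_equal(lr_schedule(49, cfg), 1e-3 * 0.95^49)
  expect_equal(lr_schedule(50, cfg), 1e-4)
  expect_equal(lr_schedule(99, cfg), 1e-4 * 0.95^49)
  expect_equal(lr_schedule(100, cfg), 1e-4)
  expect_equal(lr_schedule(150, cfg), 1e-4)
  # whole range agrees with the closed form
  ep <- 0:199
  expected <- ifelse(ep < 50, 1e-3 * 0.95^ep, 1e-4 * 0.95^(ep %% 50))
  expect_equal(lr_schedule(ep, cfg), expected)
  expect_error(lr_schedule(200, cfg), "out of range")
  expect_error(lr_schedule(-1, cfg), "out of range")
  # constant-within-cycle variant
  cfg2 <- train_config(decay_within_cycle = FALSE)
  expect_equal(lr_schedule(75, cfg2), 1e-4)
})

test_that("augmentation applies bounded scaling and exact rotations", {
  set.seed(7)
  img <- array(runif(40 * 60 * 3), dim = c(40, 60, 3))
  cfg <- train_config()
  scales <- replicate(200, {
    d <- dim(augment_image(img, cfg))
    # right-angle rotation may swap the axes; recover the common factor
    c(min(d[1:2]) / 40, max(d[1:2]) / 60)
  })
  # scale factors stay within [0.8, 1.2] (dimension rounding aside)
  expect_true(all(scales >= 0.8 - 0.05 & scales <= 1.2 + 0.05))
  off <- train_config(augment = FALSE)
  expect_identical(augment_image(img, off), img)
  set.seed(99); a1 <- augment_image(img, cfg)
  set.seed(99); a2 <- augment_image(img, cfg)
  expect_identical(a1, a2)
  # right-angle rotation is exact
  expect_identical(wsiattn:::rotate90(wsiattn:::rotate90(img, 2), 2), img)
  expect_equal(dim(wsiattn:::rotate90(img, 1)), c(60L, 40L, 3L))
})

test_that("training reduces loss and consumes labels only", {
  ds <- generate_dataset(24, width = 96, height = 72, seed = 55)
  manifest <- ds$manifest
  # no box annotations anywhere near the training path
  expect_false("boxes" %in% names(manifest))
  cfg <- train_config(total_epochs = 6, val_fraction = 0.2, seed = 3)
  fit <- wsi_attention(manifest, backbone = "cnn", k = 8, cell_px = 24,
                       out_px = 16, n_filters = 4, config = cfg)
  expect_s3_class(fit, "wsi_attention")
  expect_equal(nrow(fit$log), 6L)
  expect_lt(fit$log$loss[6], fit$log$loss[1])
  # slide-level split: no slide in both sets
  tr_slides <- manifest$slide_id[manifest$tissue_id %in% fit$split$train]
  va_slides <- manifest$slide_id[manifest$tissue_id %in% fit$split$validation]
  expect_length(intersect(tr_slides, va_slides), 0L)
})

test_that("variable grid shapes coexist in one batch", {
  ds1 <- generate_dataset(4, width = 96, height = 72, seed = 56)
  ds2 <- generate_dataset(4, width = 72, height = 96, seed = 57)
  ds2$manifest$tissue_id <- paste0(ds2$manifest$tissue_id, "b")
  ds2$manifest$slide_id <- paste0(ds2$manifest$slide_id, "b")
  manifest <- rbind(ds1$manifest, ds2$manifest)
  cfg <- train_config(total_epochs = 2, val_fraction = 0.25, seed = 4)
  fit <- wsi_attention(manifest, backbone = "cnn", k = 8, cell_px = 24,
                       out_px = 16, n_filters = 4, config = cfg)
  expect_true(all(is.finite(fit$log$loss)))
})

test_that("training runs from a PNG-backed manifest on disk", {
  out <- file.path(tempdir(), "wsiattn-disk-train")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  generate_dataset(8, out_dir = out, width = 96, height = 72, seed = 59)
  m <- read_manifest(file.path(out, "manifest.csv"))
  expect_null(m[["image"]])
  img <- wsiattn:::load_manifest_image(m, 1, data_dir = out)
  expect_equal(dim(img), c(72L, 96L, 3L))      # pixels, not a path
  cfg <- train_config(total_epochs = 1, val_fraction = 0.25, seed = 8)
  fit <- wsi_attention(m, data_dir = out, backbone = "cnn", k = 8,
                       cell_px = 24, out_px = 16, n_filters = 4,
                       config = cfg)
  expect_true(is.finite(fit$log$loss[1]))
})

test_that("the fitted object exposes the standard methods", {
  ds <- generate_dataset(10, width = 96, height = 72, seed = 58)
  cfg <- train_config(total_epochs = 2, val_fraction = 0.2, seed = 5)
  fit <- wsi_attention(ds$manifest, backbone = "cnn", k = 8, cell_px = 24,
                       out_px = 16, n_filters = 4, config = cfg)
  expect_output(print(fit), "Attention-based tissue classifier")
  expect_output(print(summary(fit)), "parameters")
  co <- coef(fit)
  expect_equal(dim(co), c(4 * 8, 4L))
  expect_equal(colnames(co), class_order())
  pr <- predict(fit, ds$manifest, type = "prob")
  expect_equal(rowSums(as.matrix(pr)), rep(1, 10), tolerance = 1e-9)
  cl <- predict(fit, ds$manifest, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), class_order())
})
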