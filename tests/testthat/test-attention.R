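# The 3-D convolutional attention module and the model head.

test_that("attention logits match the nested-loop oracle", {
  set.seed(41)
  U <- array(rnorm(4 * 5 * 8), dim = c(4, 5, 8))
  W <- array(rnorm(3 * 3 * 8 * 3), dim = c(3, 3, 8, 3))
  b <- rnorm(3)
  expect_lt(max(abs(compute_attention_logits(U, W, b) -
                    oracle_attention_logits(U, W, b))), 1e-5)
})

test_that("attention logits degenerate cases", {
  U <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  W0 <- array(0, dim = c(3, 3, 4, 2))
  expect_equal(max(abs(compute_attention_logits(U, W0, c(0, 0)))), 0)
  b <- c(1.5, -2)
  lg <- compute_attention_logits(array(0, dim = c(2, 3, 4)), W0 + 0.3, b)
  expect_equal(as.vector(lg[1, , ]), rep(1.5, 6))
  expect_equal(as.vector(lg[2, , ]), rep(-2, 6))
  Wbad <- array(0, dim = c(3, 3, 5, 2))
  expect_error(compute_attention_logits(U, Wbad, b), "depth mismatch")
})

test_that("softmax normalization yields probability maps per head", {
  lg <- array(2.5, dim = c(3, 2, 3))
  al <- normalize_attention(lg)
  expect_equal(as.vector(al), rep(1 / 6, 18))
  lg2 <- array(c(0, log(3)), dim = c(1, 1, 2))
  expect_equal(as.vector(normalize_attention(lg2)), c(0.25, 0.75))
  set.seed(42)
  lg3 <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5))
  expect_equal(normalize_attention(lg3 + 100), normalize_attention(lg3),
               tolerance = 1e-12)
  al3 <- normalize_attention(lg3)
  expect_true(all(al3 >= 0))
  expect_equal(apply(al3, 1, sum), rep(1, 4), tolerance = 1e-12)
})

test_that("attend is the affine combination of cell features", {
  set.seed(43)
  U <- array(rnorm(3 * 4 * 6), dim = c(3, 4, 6))
  al <- normalize_attention(array(rnorm(2 * 3 * 4), dim = c(2, 3, 4)))
  expect_lt(max(abs(attend(U, al) - oracle_attend(U, al))), 1e-6)
  # all cells equal: any attention returns that vector
  v <- rnorm(6)
  Ueq <- array(rep(v, each = 12), dim = c(3, 4, 6))
  expect_equal(attend(Ueq, al), rep(v, 2), tolerance = 1e-12)
  # one-hot attention selects one cell
  hot <- array(0, dim = c(1, 3, 4)); hot[1, 2, 3] <- 1
  expect_equal(attend(U, hot), U[2, 3, ], tolerance = 1e-12)
})

test_that("context classification: dropout semantics and normalization", {
  set.seed(44)
  z <- rnorm(12)
  W <- wsiattn:::init_glorot(12, 4); b <- rnorm(4)
  e1 <- classify_context(z, W, b, dropout_p = 0.5, training = FALSE)
  e2 <- classify_context(z, W, b, dropout_p = 0.5, training = FALSE)
  expect_identical(e1$probs, e2$probs)
  expect_equal(sum(e1$probs), 1, tolerance = 1e-9)
  t0 <- classify_context(z, W, b, dropout_p = 0, training = TRUE)
  expect_equal(t0$probs, e1$probs, tolerance = 1e-12)
  tr <- classify_context(z, W, b, dropout_p = 0.5, training = TRUE)
  expect_false(is.null(tr$mask))
})

test_that("per-head context vectors lie in the convex hull of cells", {
  set.seed(45)
  model <- tiny_model(k = 6, n_filters = 4, px = 8)
  cells <- random_cells(8, 12, seed = 45)
  fw <- model_forward(model, cells, shape = c(3, 4))
  k <- 6
  lo <- apply(grid_to_feat(fw$U), 1, min)
  hi <- apply(grid_to_feat(fw$U), 1, max)
  for (f in 1:4) {
    zf <- fw$z[((f - 1) * k + 1):(f * k)]
    expect_true(all(zf >= lo - 1e-9 & zf <= hi + 1e-9))
  }
})

test_that("transpose equivariance holds for symmetric kernels", {
  set.seed(46)
  U <- array(rnorm(3 * 5 * 4), dim = c(3, 5, 4))
  W <- array(rnorm(3 * 3 * 4 * 2), dim = c(3, 3, 4, 2))
  W <- (W + aperm(W, c(2, 1, 3, 4))) / 2       # symmetrize spatially
  b <- rnorm(2)
  Ut <- aperm(U, c(2, 1, 3))
  lg <- compute_attention_logits(U, W, b)
  lgt <- compute_attention_logits(Ut, W, b)
  expect_equal(lgt, aperm(lg, c(1, 3, 2)), tolerance = 1e-10)
  al <- normalize_attention(lg)
  alt <- normalize_attention(lgt)
  expect_equal(alt, aperm(al, c(1, 3, 2)), tolerance = 1e-10)
  expect_equal(attend(Ut, alt), attend(U, al), tolerance = 1e-10)
})

test_that("one grid-size-agnostic model instance handles 2x3, 3x4, 6x6", {
  model <- tiny_model(k = 6, n_filters = 3, px = 8)
  dims <- list(c(2, 3), c(3, 4), c(6, 6))
  outs <- lapply(dims, function(sh) {
    model_forward(model, random_cells(8, prod(sh), seed = sum(sh)),
                  shape = sh)
  })
  for (i in seq_along(outs)) {
    expect_length(outs[[i]]$probs, 4L)
    expect_length(outs[[i]]$z, 3 * 6)
    expect_equal(dim(outs[[i]]$alpha), c(3L, dims[[i]]))
    expect_equal(sum(outs[[i]]$probs), 1, tolerance = 1e-9)
  }
})

test_that("loss gradients are nonzero and match finite differences", {
  set.seed(47)
  model <- tiny_model(k = 5, n_filters = 2, px = 8)
  cells <- random_cells(8, 6, seed = 47)
  lg <- model_loss_grads(model, cells, c(2, 3), y_index = 4,
                         training = FALSE)
  expect_gt(max(abs(lg$grads$attn.W)), 0)
  expect_gt(max(abs(lg$grads$clf.W)), 0)
  flat <- model_params(model)
  eps <- 1e-5
  for (nm in c("attn.W", "clf.W", "attn.b")) {
    set.seed(48)
    idx <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
    for (ii in idx) {
      p2 <- flat
      p2[[nm]][ii] <- p2[[nm]][ii] + eps
      hi <- model_loss_grads(model_set_params(model, p2), cells, c(2, 3), 4,
                             training = FALSE)$loss
      p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
      lo <- model_loss_grads(model_set_params(model, p2), cells, c(2, 3), 4,
                             training = FALSE)$loss
      fd <- (hi - lo) / (2 * eps)
      expect_equal(lg$grads[[nm]][ii], fd, tolerance = 1e-4)
    }
  }
})

test_that("an optimizer step moves attention and classifier weights", {
  set.seed(49)
  model <- tiny_model(k = 5, n_filters = 2, px = 8, freeze = TRUE)
  cells <- random_cells(8, 6, seed = 49)
  lg <- model_loss_grads(model, cells, c(2, 3), y_index = 1)
  flat <- model_params(lg$model, trainable_only = TRUE)
  upd <- adam_step(flat, lg$grads, adam_init(flat), lr = 1e-2)
  model2 <- model_set_params(lg$model, upd$params)
  expect_false(identical(model$attn$W, model2$attn$W))
  expect_false(identical(model$clf$W, model2$clf$W))
})
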