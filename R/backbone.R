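# Feature-extraction backbones.
#
# A backbone maps each normalized out_px x out_px x 3 grid cell to a
# k-vector; the same weights are shared across all cells, and cells are
# processed as one batch so batch-norm statistics (where present) are taken
# over the cells of the image.  Backbones expose named stages so the freeze
# policy ("freeze everything except the last block") can address them.
#
# Two architectures ship with the package: a residual network with
# batch-normalized residual blocks (the full-scale architecture family),
# and a small 3-layer CNN used for desk-scale experiments where the whole
# pipeline must train on one CPU in minutes.

layer_conv <- function(cin, cout, ksize = 3, pad = 1) {
  list(type = "conv", W = init_msra(ksize, ksize, cin, cout),
       b = numeric(cout), pad = pad)
}
layer_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}
layer_relu <- function() list(type = "relu")
layer_pool <- function(f) list(type = "pool", f = f)
layer_gap <- function() list(type = "gap")

# Residual block: conv-bn-relu-conv-bn (+ 1x1 projection when channel
# counts differ) with a relu after the skip addition.
layer_res <- function(cin, cout) {
  l <- list(type = "res",
            conv1 = layer_conv(cin, cout), bn1 = layer_bn(cout),
            conv2 = layer_conv(cout, cout), bn2 = layer_bn(cout))
  if (cin != cout) l$proj <- layer_conv(cin, cout, ksize = 1, pad = 0)
  l
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      f <- conv2d_forward(x, layer$W, layer$b, layer$pad)
      list(out = f$out, cache = f$cache, layer = layer)
    },
    bn = {
      f <- bn_forward(x, layer$gamma, layer$beta, layer$run_mean,
                      layer$run_var, training = training)
      layer$run_mean <- f$run_mean
      layer$run_var <- f$run_var
      list(out = f$out, cache = f$cache, layer = layer)
    },
    relu = {
      f <- relu_forward(x)
      list(out = f$out, cache = f$cache, layer = layer)
    },
    pool = {
      f <- avgpool_forward(x, layer$f)
      list(out = f$out, cache = f$cache, layer = layer)
    },
    gap = {
      f <- gap_forward(x)
      list(out = f$out, cache = f$cache, layer = layer)
    },
    res = {
      c1 <- conv2d_forward(x, layer$conv1$W, layer$conv1$b, layer$conv1$pad)
      b1 <- bn_forward(c1$out, layer$bn1$gamma, layer$bn1$beta,
                       layer$bn1$run_mean, layer$bn1$run_var,
                       training = training)
      layer$bn1$run_mean <- b1$run_mean; layer$bn1$run_var <- b1$run_var
      r1 <- relu_forward(b1$out)
      c2 <- conv2d_forward(r1$out, layer$conv2$W, layer$conv2$b,
                           layer$conv2$pad)
      b2 <- bn_forward(c2$out, layer$bn2$gamma, layer$bn2$beta,
                       layer$bn2$run_mean, layer$bn2$run_var,
                       training = training)
      layer$bn2$run_mean <- b2$run_mean; layer$bn2$run_var <- b2$run_var
      if (!is.null(layer$proj)) {
        pr <- conv2d_forward(x, layer$proj$W, layer$proj$b, layer$proj$pad)
        skip <- pr$out; proj_cache <- pr$cache
      } else {
        skip <- x; proj_cache <- NULL
      }
      out <- relu_forward(b2$out + skip)
      list(out = out$out,
           cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                        c2 = c2$cache, b2 = b2$cache, proj = proj_cache,
                        relu_out = out$cache),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      b <- conv2d_backward(dout, cache)
      list(dx = b$dx, grads = list(W = b$dW, b = b$db))
    },
    bn = {
      b <- bn_backward(dout, cache)
      list(dx = b$dx, grads = list(gamma = b$dgamma, beta = b$dbeta))
    },
    relu = list(dx = relu_backward(dout, cache), grads = NULL),
    pool = list(dx = avgpool_backward(dout, cache), grads = NULL),
    gap = list(dx = gap_backward(dout, cache), grads = NULL),
    res = {
      d <- relu_backward(dout, cache$relu_out)
      b2 <- bn_backward(d, cache$b2)
      c2 <- conv2d_backward(b2$dx, cache$c2)
      r1 <- relu_backward(c2$dx, cache$r1)
      b1 <- bn_backward(r1, cache$b1)
      c1 <- conv2d_backward(b1$dx, cache$c1)
      g <- list(conv1 = list(W = c1$dW, b = c1$db),
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(W = c2$dW, b = c2$db),
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
      dx <- c1$dx
      if (!is.null(cache$proj)) {
        pr <- conv2d_backward(d, cache$proj)
        g$proj <- list(W = pr$dW, b = pr$db)
        dx <- dx + pr$dx
      } else {
        dx <- dx + d
      }
      list(dx = dx, grads = g)
    },
    stop("unknown layer type: ", layer$type))
}

#' Small convolutional backbone for desk-scale experiments
#'
#' A 3-layer CNN: a conv-relu-pool stem and a conv-relu-global-average-pool
#' head, producing a `k`-vector per cell.  Weights are drawn with He (MSRA)
#' initialization from the current RNG.
#'
#' @param k feature dimensionality per cell
#' @param width stem channel count
#' @param input_px expected cell size (must be divisible by 4)
#' @return object of class `backbone`
#' @export
backbone_cnn <- function(k = 16, width = 8, input_px = 32) {
  stopifnot(input_px %% 4 == 0)
  structure(list(
    name = "cnn",
    stages = list(
      stem = list(conv = layer_conv(3, width), relu = layer_relu(),
                  pool = layer_pool(4)),
      head = list(conv = layer_conv(width, k), relu = layer_relu(),
                  gap = layer_gap())
    ),
    stage_order = c("stem", "head"),
    k = k, width = width, input_px = input_px, frozen = character(0)),
    class = "backbone")
}

#' Residual backbone with batch normalization
#'
#' A compact residual architecture in the ResNet family: a batch-normalized
#' conv stem followed by residual blocks, ending in global average pooling.
#' The final residual block is the unit the freeze policy leaves trainable.
#' ImageNet-scale pretrained weights are not bundled; weights are randomly
#' initialized (MSRA for convolutions, unit/zero for batch norms) and any
#' externally trained checkpoint with the same shapes can be loaded in
#' their place.
#'
#' @param widths channel counts: stem, then one per residual block
#' @param input_px expected cell size (divisible by 4)
#' @return object of class `backbone` with `k = tail(widths, 1)`
#' @export
backbone_resnet <- function(widths = c(8, 16, 32), input_px = 32) {
  stopifnot(length(widths) >= 2, input_px %% 4 == 0)
  stages <- list(
    stem = list(conv = layer_conv(3, widths[1]), bn = layer_bn(widths[1]),
                relu = layer_relu(), pool = layer_pool(2))
  )
  nb <- length(widths) - 1
  for (i in seq_len(nb)) {
    nm <- paste0("block", i)
    st <- list(res = layer_res(widths[i], widths[i + 1]))
    if (i < nb) st$pool <- layer_pool(2)
    stages[[nm]] <- st
  }
  stages[[paste0("block", nb)]]$gap <- layer_gap()
  structure(list(name = "resnet", stages = stages,
                 stage_order = names(stages),
                 k = widths[length(widths)], widths = widths,
                 input_px = input_px, frozen = character(0)),
            class = "backbone")
}

#' Freeze all backbone stages except the last block
#'
#' Disables gradient updates for every stage except the final one, a
#' regularization device for small datasets: early layers keep their
#' initialization (or pretrained values) while only the last block adapts.
#' Batch-norm layers inside frozen stages always run with their stored
#' running statistics, so frozen parameters and statistics cannot drift.
#'
#' @param backbone a `backbone`
#' @param enabled set `FALSE` to unfreeze everything
#' @return the backbone with its `frozen` field set
#' @export
apply_freeze_policy <- function(backbone, enabled = TRUE) {
  if (is.null(backbone$stage_order) || length(backbone$stage_order) == 0) {
    warning("backbone has no stage structure; freeze policy is a no-op")
    return(backbone)
  }
  backbone$frozen <- if (enabled) {
    backbone$stage_order[-length(backbone$stage_order)]
  } else {
    character(0)
  }
  backbone
}

# Forward pass through all stages.  x: (px, px, 3, N).  Returns the k x N
# feature matrix, per-stage caches and the (possibly BN-updated) backbone.
backbone_forward <- function(backbone, x, training = FALSE) {
  caches <- list()
  for (st in backbone$stage_order) {
    frozen <- st %in% backbone$frozen
    st_caches <- list()
    for (ln in names(backbone$stages[[st]])) {
      f <- layer_forward(backbone$stages[[st]][[ln]], x,
                         training = training && !frozen)
      backbone$stages[[st]][[ln]] <- f$layer
      st_caches[[ln]] <- f$cache
      x <- f$out
    }
    caches[[st]] <- st_caches
  }
  list(features = x, caches = caches, backbone = backbone)
}

# Backward pass; returns flat grads named backbone.stages.<stage>.<layer>.<p>
# for trainable stages only.
backbone_backward <- function(backbone, dfeat, caches) {
  grads <- list()
  dout <- dfeat
  for (st in rev(backbone$stage_order)) {
    frozen <- st %in% backbone$frozen
    lnames <- names(backbone$stages[[st]])
    for (ln in rev(lnames)) {
      b <- layer_backward(backbone$stages[[st]][[ln]], dout, caches[[st]][[ln]])
      if (!frozen && !is.null(b$grads)) {
        flat <- flatten_params(b$grads)
        for (k in names(flat)) {
          grads[[paste("backbone.stages", st, ln, k, sep = ".")]] <- flat[[k]]
        }
      }
      dout <- b$dx
    }
  }
  list(grads = grads, dx = dout)
}

#' Extract the grid feature map U from tiled cells
#'
#' Applies the shared backbone to every grid cell and assembles the
#' r x c x k feature tensor.  Extraction is cell-local: each feature vector
#' depends only on its own cell.
#'
#' @param cells output of [tile_grid()] (after [normalize_cells()]), or a
#'   (px, px, 3, N) array with an explicit `shape`
#' @param backbone a `backbone`
#' @param shape grid shape `c(r, c)`, required when `cells` is a bare array
#' @param training forward in training mode (batch-norm batch statistics in
#'   trainable stages)
#' @return r x c x k array (the grid tensor U)
#' @export
extract_features <- function(cells, backbone, shape = NULL, training = FALSE) {
  if (is.list(cells) && !is.null(cells$cells)) {
    shape <- cells$shape
    cells <- cells$cells
  }
  stopifnot(!is.null(shape), length(dim(cells)) == 4)
  if (dim(cells)[1] != backbone$input_px) {
    stop("cell size ", dim(cells)[1], " does not match backbone input ",
         backbone$input_px)
  }
  f <- backbone_forward(backbone, cells, training = training)
  feat_to_grid(f$features, shape)
}

#' Reshape between the k x N cell-feature matrix and the grid tensor U
#'
#' Cells are ordered row-major (cell `n` maps to row `(n-1) %/% c + 1`,
#' column `(n-1) %% c + 1`).
#' @param feat k x N feature matrix
#' @param shape grid shape `c(r, c)`
#' @return r x c x k array
#' @export
feat_to_grid <- function(feat, shape) {
  r <- shape[1]; cc <- shape[2]; k <- nrow(feat)
  aperm(array(feat, dim = c(k, cc, r)), c(3, 2, 1))
}
#' @rdname feat_to_grid
#' @param U r x c x k grid tensor
#' @export
grid_to_feat <- function(U) {
  d <- dim(U)
  matrix(aperm(U, c(3, 2, 1)), nrow = d[3], ncol = d[1] * d[2])
}
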