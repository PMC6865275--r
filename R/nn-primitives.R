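# Low-level neural-network primitives.
#
# Activations are 4-D arrays (H, W, C, N): N is the "batch" axis, which for
# grid feature extraction holds the r*c cells of one tissue.  All layers have
# an explicit backward pass; caches returned by *_forward() are consumed by
# the matching *_backward().  Convolution uses im2col so the inner loop is a
# single BLAS matrix multiply.

#' Zero-pad the spatial dimensions of a batch of images
#' @param x array (H, W, C, N)
#' @param p integer padding on each spatial side
#' @param value fill value
#' @keywords internal
pad_spatial <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

# im2col: rows ordered (h fastest, then w, then n); columns ordered
# (channel fastest, then kernel row a, then kernel col b).  The weight
# matrix in conv2d_forward() is permuted to match.
im2col <- function(xp, kh, kw, hout, wout) {
  d <- dim(xp)                       # (Hp, Wp, C, N)
  cin <- d[3]; n <- d[4]
  blocks <- vector("list", kh * kw)
  idx <- 1L
  for (b in seq_len(kw)) {
    for (a in seq_len(kh)) {
      sl <- xp[a:(a + hout - 1), b:(b + wout - 1), , , drop = FALSE]
      sl <- aperm(sl, c(1, 2, 4, 3))           # (hout, wout, N, C)
      blocks[[idx]] <- matrix(sl, nrow = hout * wout * n, ncol = cin)
      idx <- idx + 1L
    }
  }
  do.call(cbind, blocks)
}

col2im <- function(dcols, dimx, kh, kw, hout, wout, p) {
  hp <- dimx[1] + 2 * p; wp <- dimx[2] + 2 * p
  cin <- dimx[3]; n <- dimx[4]
  dxp <- array(0, dim = c(hp, wp, cin, n))
  idx <- 1L
  for (b in seq_len(kw)) {
    for (a in seq_len(kh)) {
      blk <- dcols[, ((idx - 1) * cin + 1):(idx * cin), drop = FALSE]
      blk <- array(blk, dim = c(hout, wout, n, cin))
      blk <- aperm(blk, c(1, 2, 4, 3))
      dxp[a:(a + hout - 1), b:(b + wout - 1), , ] <-
        dxp[a:(a + hout - 1), b:(b + wout - 1), , , drop = FALSE] + blk
      idx <- idx + 1L
    }
  }
  if (p > 0) {
    dxp <- dxp[(p + 1):(p + dimx[1]), (p + 1):(p + dimx[2]), , , drop = FALSE]
  }
  dxp
}

#' 2-D convolution, stride 1
#'
#' @param x array (H, W, Cin, N)
#' @param W array (kh, kw, Cin, Cout)
#' @param b numeric length Cout
#' @param pad integer symmetric zero padding
#' @return list(out = (Hout, Wout, Cout, N), cache)
#' @keywords internal
conv2d_forward <- function(x, W, b, pad = 1) {
  dW <- dim(W); kh <- dW[1]; kw <- dW[2]; cin <- dW[3]; cout <- dW[4]
  dx <- dim(x)
  stopifnot(dx[3] == cin)
  hout <- dx[1] + 2 * pad - kh + 1
  wout <- dx[2] + 2 * pad - kw + 1
  stopifnot(hout >= 1, wout >= 1)
  xp <- pad_spatial(x, pad)
  cols <- im2col(xp, kh, kw, hout, wout)
  Wmat <- matrix(aperm(W, c(3, 1, 2, 4)), nrow = cin * kh * kw, ncol = cout)
  outmat <- cols %*% Wmat
  outmat <- sweep(outmat, 2, b, "+")
  out <- array(outmat, dim = c(hout, wout, dx[4], cout))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out,
       cache = list(cols = cols, Wmat = Wmat, dimx = dx, kh = kh, kw = kw,
                    hout = hout, wout = wout, pad = pad, cout = cout))
}

conv2d_backward <- function(dout, cache) {
  # dout: (Hout, Wout, Cout, N)
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)),
                 nrow = cache$hout * cache$wout * dim(dout)[4],
                 ncol = cache$cout)
  dWmat <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, cache$Wmat)
  dx <- col2im(dcols, cache$dimx, cache$kh, cache$kw,
               cache$hout, cache$wout, cache$pad)
  cin <- cache$dimx[3]
  dW <- array(dWmat, dim = c(cin, cache$kh, cache$kw, cache$cout))
  dW <- aperm(dW, c(2, 3, 1, 4))
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

#' Non-overlapping average pooling by integer factor f
#' @keywords internal
avgpool_forward <- function(x, f) {
  d <- dim(x)
  stopifnot(d[1] %% f == 0, d[2] %% f == 0)
  h2 <- d[1] %/% f; w2 <- d[2] %/% f
  m <- array(x, dim = c(f, h2, f, w2, d[3], d[4]))
  m <- aperm(m, c(1, 3, 2, 4, 5, 6))
  out <- array(colMeans(matrix(m, nrow = f * f)), dim = c(h2, w2, d[3], d[4]))
  list(out = out, cache = list(f = f, dimx = d))
}

avgpool_backward <- function(dout, cache) {
  f <- cache$f; d <- cache$dimx
  h2 <- d[1] %/% f; w2 <- d[2] %/% f
  g <- dout / (f * f)
  m <- array(rep(as.vector(g), each = f * f),
             dim = c(f, f, h2, w2, d[3], d[4]))
  array(aperm(m, c(1, 3, 2, 4, 5, 6)), dim = d)
}

#' Global average pooling: (H, W, C, N) -> C x N matrix
#' @keywords internal
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])            # (HW) x (C*N)
  out <- matrix(colMeans(m), nrow = d[3], ncol = d[4])
  list(out = out, cache = d)
}

gap_backward <- function(dout, cache) {
  d <- cache
  g <- dout / (d[1] * d[2])
  array(rep(as.vector(g), each = d[1] * d[2]), dim = d)
}

#' Batch normalization over (H, W, N) per channel
#'
#' Training mode uses the statistics of the current batch and updates running
#' statistics with the given momentum; evaluation (or frozen) mode uses the
#' stored running statistics so frozen stages cannot drift.
#' @keywords internal
bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))                 # (H, W, N, C)
  xm <- matrix(xm, ncol = d[3])                 # rows: spatial*batch, cols: C
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d,
                    training = training))
}

bn_backward <- function(dout, cache) {
  d <- cache$d
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  m <- nrow(dm)
  if (cache$training) {
    dxhat <- sweep(dm, 2, cache$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dxm <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dxm <- sweep(sweep(dm, 2, cache$gamma, "*"), 2, cache$inv, "*")
  }
  dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Fully connected layer on column vectors
#' @param x matrix (din, N)
#' @param W matrix (din, dout)
#' @keywords internal
fc_forward <- function(x, W, b) {
  out <- crossprod(W, x) + b        # (dout, N)
  list(out = out, cache = list(x = x, W = W))
}

fc_backward <- function(dout, cache) {
  list(dx = cache$W %*% dout,
       dW = cache$x %*% t(dout),
       db = rowSums(dout))
}

#' Numerically stable softmax over the first dimension
#' @keywords internal
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- sweep(x, 2, apply(x, 2, max), "-")
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

#' Cross-entropy loss with softmax, single sample
#' @param logits numeric vector
#' @param y 1-based class index
#' @return list(loss, probs, dlogits)
#' @keywords internal
ce_loss <- function(logits, y) {
  p <- softmax(logits)
  loss <- -log(max(p[y], 1e-12))
  d <- p
  d[y] <- d[y] - 1
  list(loss = loss, probs = p, dlogits = d)
}

# ---- initializers -----------------------------------------------------------

#' He (MSRA) initialization for convolutional weights
#'
#' Zero-mean normal with variance 2/fan_in, fan_in = kh*kw*Cin.
#' @keywords internal
init_msra <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin, cout))
}

#' Glorot initialization for fully connected weights
#'
#' Zero-mean normal with variance 2/(fan_in + fan_out).
#' @keywords internal
init_glorot <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))),
         nrow = din, ncol = dout)
}

# ---- parameter trees and Adam ----------------------------------------------

# Parameters live in nested named lists; these helpers flatten them to a
# named list of arrays keyed by dot-joined paths, so the optimizer and the
# freeze policy can address any tensor by name.

flatten_params <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(v)) {
      out <- c(out, flatten_params(v, c(prefix, nm)))
    } else if (is.numeric(v)) {
      out[[key]] <- v
    }
  }
  out
}

assign_param <- function(x, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, parts, value) {
    if (length(parts) == 1) {
      node[[parts]] <- value
      return(node)
    }
    node[[parts[1]]] <- rec(node[[parts[1]]], parts[-1], value)
    node
  }
  rec(x, parts, value)
}

#' Create Adam optimizer state for a flat parameter list
#' @param flat named list of parameter arrays
#' @param lr,beta1,beta2,eps the usual Adam constants
#' @return optimizer state consumed by [adam_step()]
#' @export
adam_init <- function(flat, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0))
}

#' One Adam update
#' @param flat named list of parameter arrays
#' @param grads matching named list of gradients (missing names are skipped)
#' @param state from [adam_init()]
#' @param lr learning-rate override for this step
#' @return list(params, state)
#' @export
adam_step <- function(flat, grads, state, lr = NULL) {
  if (is.null(lr)) lr <- state$lr
  state$t <- state$t + 1
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = flat, state = state)
}

# Accumulate grads2 into grads1 (both flat named lists; NULL-safe).
acc_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (k in names(g2)) {
    g1[[k]] <- if (is.null(g1[[k]])) g2[[k]] else g1[[k]] + g2[[k]]
  }
  g1
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
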