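# Soft attention over the grid feature map.
#
# The attention module applies F learnable 3-D convolutional filters of
# size k x d x d to the grid tensor U (r x c x k): the kernel spans the
# full feature depth k (no depth padding, so the depth output is 1) and a
# d x d spatial neighbourhood with zero padding (d-1)/2, preserving (r, c).
# Each filter's logit map is softmax-normalized over all r*c grid positions
# into an attention map — nonnegative weights summing to 1 — and the
# corresponding affine combination of cell feature vectors yields one
# k-dimensional context vector per filter.  The F context vectors are
# concatenated into z (length F*k), passed through dropout, and a single
# fully connected layer produces the 4 class logits.

#' Attention module configuration
#'
#' @param n_filters number of attention filters F (64 at full scale)
#' @param kernel spatial kernel size d (odd)
#' @param dropout_p dropout probability applied to the concatenated context
#'   vector during training
#' @return list of class `attention_config`
#' @export
attention_config <- function(n_filters = 64, kernel = 3, dropout_p = 0.5) {
  stopifnot(kernel %% 2 == 1, n_filters >= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(n_filters = n_filters, kernel = kernel,
                 dropout_p = dropout_p),
            class = "attention_config")
}

#' Attention logits: 3-D convolution of the filters over U
#'
#' `logits[f, i, j] = sum_{kappa, a, b} W[f][kappa, a, b] * U[i+a, j+b, kappa]
#' + bias[f]`, with zero padding of (d-1)/2 in height and width and none in
#' depth (the kernel consumes the full feature depth).
#'
#' @param U r x c x k grid tensor
#' @param filters (d, d, k, F) array of filter weights
#' @param bias numeric length F
#' @return F x r x c array of attention logits
#' @export
compute_attention_logits <- function(U, filters, bias) {
  d <- dim(U)
  df <- dim(filters)
  if (d[3] != df[3]) {
    stop("feature depth mismatch: U has k = ", d[3],
         " but filters expect k = ", df[3])
  }
  stopifnot(all(is.finite(U)))
  x <- array(U, dim = c(d[1], d[2], d[3], 1))
  f <- conv2d_forward(x, filters, bias, pad = (df[1] - 1) %/% 2)
  aperm(array(f$out, dim = dim(f$out)[1:3]), c(3, 1, 2))
}

#' Normalize attention logits into attention maps
#'
#' Per filter, a numerically stabilized softmax over all r*c grid positions,
#' giving nonnegative weights that sum to 1 — the weights of an affine
#' combination of cell feature vectors.
#'
#' @param logits F x r x c array
#' @return F x r x c array `alpha`; each head sums to 1
#' @export
normalize_attention <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1])          # F x (r*c)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  a <- e / rowSums(e)
  array(a, dim = d)
}

#' Attend: affine combination of cell features under each attention head
#'
#' For each head f, `z_f = sum_{i,j} alpha[f, i, j] * U[i, j, ]`; the
#' per-head context vectors are concatenated into one vector of length F*k
#' (head 1 first).
#'
#' @param U r x c x k grid tensor
#' @param alpha F x r x c attention maps
#' @return numeric vector z of length F*k
#' @export
attend <- function(U, alpha) {
  d <- dim(U)
  da <- dim(alpha)
  if (!all(da[2:3] == d[1:2])) stop("alpha and U grid shapes disagree")
  Umat <- matrix(U, nrow = d[1] * d[2], ncol = d[3])
  A <- matrix(alpha, nrow = da[1])
  Z <- A %*% Umat                            # F x k
  as.vector(t(Z))
}

#' Classify a context vector
#'
#' Training mode applies inverted dropout to z before the fully connected
#' layer; evaluation mode applies none.  Probabilities are a softmax over
#' the 4 class logits.
#'
#' @param z context vector (length F*k)
#' @param W (F*k) x 4 classifier weights
#' @param b length-4 bias
#' @param dropout_p dropout probability
#' @param training logical
#' @return list(probs, logits, mask) — mask is the dropout mask used (NULL
#'   in evaluation mode)
#' @export
classify_context <- function(z, W, b, dropout_p = 0.5, training = FALSE) {
  mask <- NULL
  zd <- z
  if (training && dropout_p > 0) {
    mask <- (stats::runif(length(z)) >= dropout_p) / (1 - dropout_p)
    zd <- z * mask
  }
  logits <- as.vector(crossprod(W, zd)) + b
  list(probs = softmax(logits), logits = logits, mask = mask, z_dropped = zd)
}

# ---- full model -------------------------------------------------------------

#' Assemble an attention model
#'
#' Combines a shared per-cell backbone, the 3-D convolutional attention
#' module and the linear classifier.  Attention filters are MSRA-initialized
#' (fan-in k*d*d), the classifier is Glorot-initialized, biases start at
#' zero; draws come from the current RNG.
#'
#' @param backbone a `backbone`
#' @param config an [attention_config()]
#' @param classes class labels, risk-ordered
#' @return object of class `attn_model`
#' @export
new_attn_model <- function(backbone, config = attention_config(),
                           classes = class_order()) {
  k <- backbone$k
  d <- config$kernel
  structure(list(
    backbone = backbone,
    attn = list(W = init_msra(d, d, k, config$n_filters),
                b = numeric(config$n_filters)),
    clf = list(W = init_glorot(config$n_filters * k, length(classes)),
               b = numeric(length(classes))),
    config = config,
    classes = classes), class = "attn_model")
}

#' Forward pass of the attention model on one tissue
#'
#' Composes tiling features -> attention logits -> softmax attention ->
#' affine combination -> dropout -> linear classifier.  Works for any grid
#' shape (r, c) without reconfiguration.
#'
#' @param model an `attn_model`
#' @param cells normalized cells from [tile_grid()]/[normalize_cells()]
#' @param shape grid shape when `cells` is a bare array
#' @param training forward in training mode (dropout active, batch-norm
#'   batch statistics in trainable stages)
#' @return list(probs, logits, alpha, z, U, caches, model)
#' @export
model_forward <- function(model, cells, shape = NULL, training = FALSE) {
  if (is.list(cells) && !is.null(cells$cells)) {
    shape <- cells$shape
    cells <- cells$cells
  }
  bf <- backbone_forward(model$backbone, cells, training = training)
  model$backbone <- bf$backbone
  U <- feat_to_grid(bf$features, shape)
  du <- dim(U)
  x <- array(U, dim = c(du[1], du[2], du[3], 1))
  cf <- conv2d_forward(x, model$attn$W, model$attn$b,
                       pad = (model$config$kernel - 1) %/% 2)
  logits_a <- aperm(array(cf$out, dim = dim(cf$out)[1:3]), c(3, 1, 2))
  alpha <- normalize_attention(logits_a)
  z <- attend(U, alpha)
  cl <- classify_context(z, model$clf$W, model$clf$b,
                         dropout_p = model$config$dropout_p,
                         training = training)
  list(probs = cl$probs, logits = cl$logits, alpha = alpha, z = z, U = U,
       caches = list(backbone = bf$caches, attn_conv = cf$cache,
                     alpha = alpha, shape = du, mask = cl$mask,
                     z_dropped = cl$z_dropped),
       model = model)
}

#' Cross-entropy loss and gradients for one tissue
#'
#' Runs a forward pass on one set of grid cells and backpropagates the
#' cross-entropy loss, returning flat named gradients for the attention
#' module, the classifier, and every trainable backbone stage.
#'
#' @param model an `attn_model`
#' @param cells normalized (px, px, 3, N) cell array
#' @param shape grid shape `c(r, c)`
#' @param y_index 1-based true-class index (risk order)
#' @param training forward in training mode (dropout, batch statistics)
#' @return list(loss, probs, grads, model) — `model` carries updated
#'   batch-norm running statistics when training
#' @export
model_loss_grads <- function(model, cells, shape, y_index, training = TRUE) {
  fw <- model_forward(model, cells, shape = shape, training = training)
  model <- fw$model
  ce <- ce_loss(fw$logits, y_index)
  d <- fw$caches$shape                     # (r, c, k)
  Fh <- model$config$n_filters
  k <- d[3]

  # classifier
  dlogits <- ce$dlogits
  dW_clf <- fw$caches$z_dropped %*% t(dlogits)
  db_clf <- dlogits
  dzd <- model$clf$W %*% dlogits
  dz <- if (is.null(fw$caches$mask)) as.vector(dzd) else
    as.vector(dzd) * fw$caches$mask

  # attend: z = concat_f alpha_f' U
  dZ <- t(matrix(dz, nrow = k, ncol = Fh))          # F x k
  Umat <- matrix(fw$U, nrow = d[1] * d[2], ncol = k)
  A <- matrix(fw$alpha, nrow = Fh)                  # F x (r*c)
  dA <- dZ %*% t(Umat)                              # F x (r*c)
  dU_attend <- t(A) %*% dZ                          # (r*c) x k

  # softmax over positions, per head
  s <- rowSums(A * dA)
  dlog_a <- A * (dA - s)                            # F x (r*c)

  # attention convolution
  dout <- array(t(dlog_a), dim = c(d[1], d[2], Fh, 1))
  cb <- conv2d_backward(dout, fw$caches$attn_conv)
  dU <- array(dU_attend, dim = d) + array(cb$dx, dim = d)

  grads <- list(attn.W = cb$dW, attn.b = cb$db,
                clf.W = dW_clf, clf.b = db_clf)

  # backbone (only when some stage is trainable)
  if (length(model$backbone$frozen) < length(model$backbone$stage_order)) {
    dfeat <- grid_to_feat(dU)
    bb <- backbone_backward(model$backbone, dfeat, fw$caches$backbone)
    grads <- c(grads, bb$grads)
  }
  list(loss = ce$loss, probs = ce$probs, grads = grads, model = model)
}

#' Flat named parameter list of a model
#'
#' Parameters are keyed by dot-joined paths (e.g. `attn.W`,
#' `backbone.stages.head.conv.W`) shared with the gradient lists from
#' [model_loss_grads()]; frozen backbone stages are excluded when
#' `trainable_only`.
#'
#' @param model an `attn_model`
#' @param trainable_only drop parameters of frozen stages
#' @return named list of numeric arrays
#' @export
model_params <- function(model, trainable_only = FALSE) {
  flat <- c(list(attn.W = model$attn$W, attn.b = model$attn$b,
                 clf.W = model$clf$W, clf.b = model$clf$b),
            flatten_params(list(backbone =
                                  list(stages = model$backbone$stages))))
  if (trainable_only && length(model$backbone$frozen) > 0) {
    drop <- paste0("backbone.stages.", model$backbone$frozen, ".")
    keep <- !Reduce(`|`, lapply(drop, function(p) startsWith(names(flat), p)))
    flat <- flat[keep]
  }
  flat
}

#' Write a flat parameter list back into a model
#' @param model an `attn_model`
#' @param flat named list as returned by [model_params()]
#' @return the updated model
#' @export
model_set_params <- function(model, flat) {
  for (nm in names(flat)) {
    if (nm == "attn.W") model$attn$W <- flat[[nm]]
    else if (nm == "attn.b") model$attn$b <- flat[[nm]]
    else if (nm == "clf.W") model$clf$W <- flat[[nm]]
    else if (nm == "clf.b") model$clf$b <- flat[[nm]]
    else if (startsWith(nm, "backbone.stages.")) {
      parts <- strsplit(sub("^backbone\\.stages\\.", "", nm), ".",
                        fixed = TRUE)[[1]]
      model$backbone$stages <- assign_param(model$backbone$stages,
                                            paste(parts, collapse = "."),
                                            flat[[nm]])
    }
  }
  model
}
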