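# Model fitting: the package's main entry point and its S3 methods.

#' Fit the attention-based tissue classifier
#'
#' Trains the weakly supervised attention model end-to-end from tissue-level
#' labels alone.  Each tissue is tiled into a grid of cells, a shared
#' convolutional backbone extracts per-cell features, 3-D convolutional
#' attention filters produce per-filter attention maps over the grid, and
#' their affine combinations of cell features are concatenated, passed
#' through dropout and a linear layer, and trained with cross-entropy
#' against the tissue label.  Lesion bounding boxes are never read on this
#' path: the attention maps localize diagnostic regions on their own.
#'
#' Slides are split into training and validation sets keeping all tissues
#' from one slide together; channel normalization statistics are computed
#' over the training tissues only; the backbone freeze policy (all stages
#' frozen except the last block) is applied unless `freeze = FALSE`; the
#' model checkpoint with the best validation accuracy is returned.
#'
#' @param manifest data frame with columns `tissue_id`, `slide_id`, `label`
#'   and either `image` (list of (H, W, 3) arrays) or `image_path`
#' @param data_dir directory that `image_path` entries are relative to
#' @param backbone a `backbone` object, or `"cnn"` / `"resnet"` to build one
#' @param k feature dimensionality when building the backbone
#' @param cell_px,out_px grid cell size and resized cell size
#' @param n_filters number of attention filters
#' @param dropout_p dropout on the concatenated context vector
#' @param config a [train_config()]
#' @param epochs convenience override of `config$total_epochs`
#' @param freeze apply the freeze policy to the backbone
#' @param verbose print a line per epoch
#' @return object of class `wsi_attention` with components `model`
#'   (weights), `stats` (channel statistics), `log` (per-epoch data frame),
#'   `config`, `classes`, and the train/validation split
#' @seealso [predict.wsi_attention()], [attention_maps()]
#' @export
wsi_attention <- function(manifest, data_dir = NULL,
                          backbone = c("cnn", "resnet"), k = 16,
                          cell_px = 492, out_px = 224, n_filters = 8,
                          dropout_p = 0.5, config = train_config(),
                          epochs = NULL, freeze = TRUE, verbose = FALSE) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1,
            all(c("tissue_id", "slide_id", "label") %in% names(manifest)))
  validate_classes(manifest$label)
  if (!is.null(epochs)) config$total_epochs <- epochs
  set.seed(config$seed)

  # slide-level split: all tissues from one slide stay in the same set
  slides <- unique(manifest$slide_id)
  n_val <- max(1, round(config$val_fraction * length(slides)))
  if (length(slides) < 2) n_val <- 0
  val_slides <- if (n_val > 0) sample(slides, n_val) else character(0)
  is_val <- manifest$slide_id %in% val_slides
  train_idx <- which(!is_val)
  val_idx <- which(is_val)
  if (length(train_idx) == 0) stop("no training tissues after split")

  train_images <- lapply(train_idx, load_manifest_image,
                         manifest = manifest, data_dir = data_dir)
  stats <- compute_normalization_stats(train_images)

  if (is.character(backbone)) {
    backbone <- switch(match.arg(backbone),
                       cnn = backbone_cnn(k = k, input_px = out_px),
                       resnet = backbone_resnet(input_px = out_px))
  }
  backbone <- apply_freeze_policy(backbone, enabled = freeze)
  model <- new_attn_model(backbone,
                          attention_config(n_filters = n_filters,
                                           dropout_p = dropout_p))
  model <- initialize_weights(model)
  y_all <- class_rank(manifest$label)

  flat <- model_params(model, trainable_only = TRUE)
  opt <- adam_init(flat)
  log_rows <- vector("list", config$total_epochs)
  best <- list(acc = -Inf, params = NULL)

  eval_val <- function(model) {
    if (length(val_idx) == 0) return(NA_real_)
    correct <- 0
    for (i in val_idx) {
      img <- load_manifest_image(manifest, i, data_dir)
      tg <- normalize_cells(tile_grid(img, cell_px, out_px), stats)
      fw <- model_forward(model, tg, training = FALSE)
      pred <- argmax_lowest_risk(fw$probs)
      if (pred == y_all[i]) correct <- correct + 1
    }
    correct / length(val_idx)
  }

  for (epoch in seq_len(config$total_epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    ord <- sample(train_idx)
    epoch_loss <- 0
    nb <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
      grads <- NULL
      batch_loss <- 0
      for (i in batch) {
        img <- load_manifest_image(manifest, i, data_dir)
        if (config$augment) img <- augment_image(img, config)
        tg <- normalize_cells(tile_grid(img, cell_px, out_px), stats)
        lg <- model_loss_grads(model, tg$cells, tg$shape, y_all[i],
                               training = TRUE)
        model <- lg$model
        if (!is.finite(lg$loss)) {
          stop("non-finite loss at epoch ", epoch, ", tissue ",
               manifest$tissue_id[i])
        }
        grads <- acc_grads(grads, lg$grads)
        batch_loss <- batch_loss + lg$loss
      }
      grads <- scale_grads(grads, 1 / length(batch))
      flat <- model_params(model, trainable_only = TRUE)
      upd <- adam_step(flat, grads, opt, lr = lr)
      model <- model_set_params(model, upd$params)
      opt <- upd$state
      epoch_loss <- epoch_loss + batch_loss
      nb <- nb + length(batch)
    }
    val_acc <- eval_val(model)
    log_rows[[epoch + 1]] <- data.frame(epoch = epoch,
                                        loss = epoch_loss / nb,
                                        lr = lr, val_acc = val_acc)
    if (!is.na(val_acc) && val_acc >= best$acc) {
      best <- list(acc = val_acc, params = model_params(model))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  val_acc %s",
                      epoch, epoch_loss / nb, lr,
                      ifelse(is.na(val_acc), "NA", sprintf("%.3f", val_acc))))
    }
  }
  if (!is.null(best$params)) model <- model_set_params(model, best$params)

  structure(list(model = model, stats = stats,
                 log = do.call(rbind, log_rows), config = config,
                 classes = model$classes, cell_px = cell_px,
                 out_px = out_px,
                 split = list(train = manifest$tissue_id[train_idx],
                              validation = manifest$tissue_id[val_idx]),
                 best_val_acc = best$acc,
                 call = match.call()),
            class = "wsi_attention")
}

# Deterministic argmax with the conservative tie-break: among equal
# maxima the lowest-risk class wins.
argmax_lowest_risk <- function(probs) {
  which(probs >= max(probs) - 1e-12)[1]
}

#' @export
print.wsi_attention <- function(x, ...) {
  cat("Attention-based tissue classifier (wsi_attention)\n")
  cat("  classes:   ", paste(x$classes, collapse = " < "), "\n")
  cat("  backbone:  ", x$model$backbone$name, " (k = ", x$model$backbone$k,
      "), frozen stages: ",
      if (length(x$model$backbone$frozen)) {
        paste(x$model$backbone$frozen, collapse = ", ")
      } else "none", "\n", sep = "")
  cat("  attention: ", x$model$config$n_filters, " filters of ",
      x$model$backbone$k, " x ", x$model$config$kernel, " x ",
      x$model$config$kernel, ", dropout ", x$model$config$dropout_p,
      "\n", sep = "")
  cat("  grid:      ", x$cell_px, "-px cells resized to ", x$out_px,
      " px\n", sep = "")
  cat("  epochs:    ", nrow(x$log), "; final loss ",
      sprintf("%.4f", x$log$loss[nrow(x$log)]), "\n", sep = "")
  if (is.finite(x$best_val_acc)) {
    cat("  best validation accuracy: ", sprintf("%.3f", x$best_val_acc),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.wsi_attention <- function(object, ...) {
  out <- list(fit = object,
              n_params = sum(vapply(model_params(object$model), length, 0L)),
              n_trainable = sum(vapply(model_params(object$model,
                                                    trainable_only = TRUE),
                                       length, 0L)),
              log = object$log)
  class(out) <- "summary.wsi_attention"
  out
}

#' @export
print.summary.wsi_attention <- function(x, ...) {
  print(x$fit)
  cat("  parameters: ", x$n_params, " total, ", x$n_trainable,
      " trainable\n", sep = "")
  tail_log <- utils::tail(x$log, 5)
  cat("  last epochs:\n")
  print(tail_log, row.names = FALSE)
  invisible(x)
}

#' Classifier coefficients
#'
#' Returns the weights of the final fully connected layer, one column per
#' class, rows blocked by attention filter (filter 1 first, `k` rows each).
#' @param object a fitted `wsi_attention`
#' @param ... unused
#' @export
coef.wsi_attention <- function(object, ...) {
  W <- object$model$clf$W
  colnames(W) <- object$classes
  W
}

#' Predict tissue classes, probabilities and attention maps
#'
#' @param object a fitted `wsi_attention`
#' @param newdata a manifest data frame, a list of images, or one
#'   (H, W, 3) array
#' @param type "class", "prob", or "attention" (returns classes,
#'   probabilities and per-head attention maps per tissue)
#' @param data_dir directory for relative `image_path` entries
#' @param ... unused
#' @return for "class": factor vector; "prob": data frame of class
#'   probabilities; "attention": list per tissue with `class`, `probs`,
#'   `alpha` (F x r x c) and grid `shape`
#' @export
predict.wsi_attention <- function(object, newdata,
                                  type = c("class", "prob", "attention"),
                                  data_dir = NULL, ...) {
  type <- match.arg(type)
  images <- coerce_images(newdata, data_dir)
  res <- vector("list", length(images))
  for (i in seq_along(images)) {
    tg <- normalize_cells(tile_grid(images[[i]], object$cell_px,
                                    object$out_px), object$stats)
    fw <- model_forward(object$model, tg, training = FALSE)
    cls <- object$classes[argmax_lowest_risk(fw$probs)]
    res[[i]] <- list(class = cls, probs = fw$probs, alpha = fw$alpha,
                     shape = tg$shape, z = fw$z)
  }
  switch(type,
    class = factor(vapply(res, `[[`, "", "class"), levels = object$classes),
    prob = {
      m <- do.call(rbind, lapply(res, `[[`, "probs"))
      colnames(m) <- object$classes
      as.data.frame(m)
    },
    attention = res)
}

# Accept a manifest, list of arrays, or one array.
coerce_images <- function(newdata, data_dir = NULL) {
  if (is.data.frame(newdata)) {
    lapply(seq_len(nrow(newdata)), load_manifest_image,
           manifest = newdata, data_dir = data_dir)
  } else if (is.array(newdata) && length(dim(newdata)) == 3) {
    list(newdata)
  } else if (is.list(newdata)) {
    lapply(newdata, function(x) {
      if (is.list(x) && !is.null(x$pixels)) x$pixels else x
    })
  } else {
    stop("newdata must be a manifest data frame, a list of images, ",
         "or a single (H, W, 3) array")
  }
}

#' Plot training curves or an attention overlay
#'
#' Without an image, plots the training loss and validation accuracy per
#' epoch.  With `image`, renders the selected attention head over the
#' tissue as a translucent heat overlay.
#'
#' @param x a fitted `wsi_attention`
#' @param image optional (H, W, 3) array to overlay attention on
#' @param head attention head index; defaults to the head most associated
#'   with the tissue's predicted class
#' @param ... unused
#' @export
plot.wsi_attention <- function(x, image = NULL, head = NULL, ...) {
  if (is.null(image)) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                   ylab = "training loss", main = "loss")
    if (!all(is.na(x$log$val_acc))) {
      graphics::plot(x$log$epoch, x$log$val_acc, type = "l", xlab = "epoch",
                     ylab = "validation accuracy", main = "validation")
    }
    return(invisible(x))
  }
  pr <- predict(x, image, type = "attention")[[1]]
  if (is.null(head)) head <- select_class_head(x, pr$class)
  ren <- render_attention(pr$alpha[head, , ], dim(image)[1:2], x$cell_px)
  graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "",
                 ylab = "", main = paste("attention:", pr$class))
  graphics::rasterImage(image, 0, 0, 1, 1)
  heat <- grDevices::rgb(1, 0, 0, alpha = 0.5 * ren)
  dim(heat) <- dim(ren)
  graphics::rasterImage(heat, 0, 0, 1, 1)
  invisible(x)
}
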