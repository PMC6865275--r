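# Sliding-window baseline: an ROI-crop classifier plus thresholded
# heuristic aggregation of window predictions, with a validation grid
# search over the heuristic's thresholds.  Unlike the attention model,
# this path *requires* lesion bounding-box annotations for training.

#' Build a labeled crop set from ROI boxes
#'
#' Samples fixed-size crops whose centers lie inside annotated lesion
#' boxes (labeled with the box class) and crops from lesion-free tissues
#' (labeled normal).  Boxes smaller than the crop size in either dimension
#' are skipped with a warning.  Crop windows are clamped inside the image.
#'
#' @param manifest tissue manifest (see [wsi_attention()])
#' @param boxes lesion-box data frame with `tissue_id`, `class`, and pixel
#'   coordinates
#' @param crop_px crop size in pixels
#' @param per_box crops sampled per usable box
#' @param per_normal crops sampled per lesion-free tissue
#' @param seed RNG seed
#' @param data_dir directory for relative image paths
#' @return list(crops = (crop_px, crop_px, 3, N) array, labels, centers)
#' @export
make_crop_set <- function(manifest, boxes, crop_px = 224, per_box = 4,
                          per_normal = 4, seed = 1, data_dir = NULL) {
  if (is.null(boxes) || nrow(boxes) == 0) {
    stop("the sliding-window baseline requires lesion bounding-box ",
         "annotations; none were supplied (the attention model needs none)")
  }
  set.seed(seed)
  crops <- list()
  labels <- character(0)
  centers <- list()
  half <- crop_px / 2
  clamp_window <- function(center, size) {
    lo <- round(center - half)
    lo <- max(1, min(lo, size - crop_px + 1))
    lo:(lo + crop_px - 1)
  }
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    img <- load_manifest_image(manifest, i, data_dir)
    d <- dim(img)
    bx <- boxes[boxes$tissue_id == manifest$tissue_id[i], , drop = FALSE]
    if (nrow(bx) == 0) {
      if (d[1] < crop_px || d[2] < crop_px) next
      for (s in seq_len(per_normal)) {
        cx <- stats::runif(1, 0.3 * d[2], 0.7 * d[2])
        cy <- stats::runif(1, 0.3 * d[1], 0.7 * d[1])
        crops[[length(crops) + 1]] <-
          img[clamp_window(cy, d[1]), clamp_window(cx, d[2]), , drop = FALSE]
        labels <- c(labels, "normal")
        centers[[length(centers) + 1]] <-
          data.frame(tissue_id = manifest$tissue_id[i], x = cx, y = cy,
                     class = "normal")
      }
      next
    }
    for (b in seq_len(nrow(bx))) {
      if (bx$x_max[b] - bx$x_min[b] < crop_px ||
          bx$y_max[b] - bx$y_min[b] < crop_px) {
        skipped <- skipped + 1L
        next
      }
      for (s in seq_len(per_box)) {
        cx <- stats::runif(1, bx$x_min[b], bx$x_max[b])
        cy <- stats::runif(1, bx$y_min[b], bx$y_max[b])
        crops[[length(crops) + 1]] <-
          img[clamp_window(cy, d[1]), clamp_window(cx, d[2]), , drop = FALSE]
        labels <- c(labels, bx$class[b])
        centers[[length(centers) + 1]] <-
          data.frame(tissue_id = manifest$tissue_id[i], x = cx, y = cy,
                     class = bx$class[b])
      }
    }
  }
  if (skipped > 0) {
    warning(skipped, " box(es) smaller than the ", crop_px,
            "-px crop size were skipped")
  }
  if (length(crops) == 0) stop("no usable crops")
  arr <- array(0, dim = c(crop_px, crop_px, 3, length(crops)))
  for (i in seq_along(crops)) arr[, , , i] <- crops[[i]]
  list(crops = arr, labels = labels, centers = do.call(rbind, centers))
}

# Color jitter + random flips + right-angle rotations on a crop batch.
augment_crops <- function(x) {
  n <- dim(x)[4]
  for (i in seq_len(n)) {
    crop <- x[, , , i]
    jit <- stats::runif(3, -0.05, 0.05)
    for (ch in 1:3) crop[, , ch] <- pmin(pmax(crop[, , ch] + jit[ch], 0), 1)
    if (stats::runif(1) < 0.5) crop <- crop[dim(crop)[1]:1, , , drop = FALSE]
    if (stats::runif(1) < 0.5) crop <- crop[, dim(crop)[2]:1, , drop = FALSE]
    crop <- rotate90(crop, sample.int(4, 1) - 1)
    x[, , , i] <- crop
  }
  x
}

#' Train the cropped-image classifier
#'
#' A 4-class classifier on fixed-size crops: MSRA-initialized backbone,
#' cross-entropy loss, Adam with L2 weight regularization and step
#' learning-rate decay, color-jitter/flip/rotation augmentation.
#'
#' @param crop_set from [make_crop_set()]
#' @param epochs training epochs (100 at full scale)
#' @param k backbone feature dimensionality
#' @param batch_size crops per step
#' @param lr0 initial learning rate
#' @param weight_decay L2 coefficient applied to weight tensors
#' @param lr_step,lr_factor step decay: multiply by `lr_factor` every
#'   `lr_step` epochs
#' @param augment apply augmentation
#' @param seed RNG seed
#' @param verbose print per-epoch loss
#' @return object of class `crop_classifier`
#' @export
train_crop_classifier <- function(crop_set, epochs = 100, k = 16,
                                  batch_size = 16, lr0 = 1e-3,
                                  weight_decay = 1e-4, lr_step = 50,
                                  lr_factor = 0.1, augment = TRUE,
                                  seed = 1, verbose = FALSE) {
  labels <- crop_set$labels
  validate_classes(labels)
  if (length(unique(labels)) < 2) stop("crop set must span >= 2 classes")
  set.seed(seed)
  crop_px <- dim(crop_set$crops)[1]
  stats <- compute_normalization_stats(
    lapply(seq_len(dim(crop_set$crops)[4]),
           function(i) crop_set$crops[, , , i]))
  backbone <- backbone_cnn(k = k, input_px = crop_px)
  clf <- list(W = init_glorot(k, 4), b = numeric(4))
  y <- class_rank(labels)
  n <- length(y)
  params <- c(flatten_params(list(backbone =
                                    list(stages = backbone$stages))),
              list(clf.W = clf$W, clf.b = clf$b))
  opt <- adam_init(params)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr0 * lr_factor^floor((ep - 1) / lr_step)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- crop_set$crops[, , , idx, drop = FALSE]
      if (augment) xb <- augment_crops(xb)
      for (ch in 1:3) {
        xb[, , ch, ] <- (xb[, , ch, ] - stats$mean[ch]) / stats$sd[ch]
      }
      bf <- backbone_forward(backbone, xb, training = TRUE)
      backbone <- bf$backbone
      fc <- fc_forward(bf$features, clf$W, clf$b)
      probs <- softmax(fc$out)
      m <- length(idx)
      pick <- cbind(y[idx], seq_len(m))
      ep_loss <- ep_loss + sum(-log(pmax(probs[pick], 1e-12)))
      dlogits <- probs
      dlogits[pick] <- dlogits[pick] - 1
      dlogits <- dlogits / m
      fb <- fc_backward(dlogits, fc$cache)
      bb <- backbone_backward(backbone, fb$dx, bf$caches)
      grads <- c(bb$grads, list(clf.W = fb$dW, clf.b = fb$db))
      params <- c(flatten_params(list(backbone =
                                        list(stages = backbone$stages))),
                  list(clf.W = clf$W, clf.b = clf$b))
      if (weight_decay > 0) {
        for (nm in names(grads)) {
          if (endsWith(nm, ".W") || nm == "clf.W") {
            grads[[nm]] <- grads[[nm]] + weight_decay * params[[nm]]
          }
        }
      }
      upd <- adam_step(params, grads, opt, lr = lr)
      opt <- upd$state
      params <- upd$params
      st <- list(stages = backbone$stages)
      for (nm in names(params)) {
        if (startsWith(nm, "backbone.stages.")) {
          st$stages <- assign_param(st$stages,
                                    sub("^backbone\\.stages\\.", "", nm),
                                    params[[nm]])
        }
      }
      backbone$stages <- st$stages
      clf$W <- params$clf.W
      clf$b <- params$clf.b
    }
    loss_trace[ep] <- ep_loss / n
    if (verbose) message(sprintf("crop epoch %3d  loss %.4f", ep,
                                 loss_trace[ep]))
  }
  structure(list(backbone = backbone, clf = clf, stats = stats,
                 crop_px = crop_px, classes = class_order(),
                 loss_trace = loss_trace),
            class = "crop_classifier")
}

#' Classify crops with a trained crop classifier
#' @param object a `crop_classifier`
#' @param crops (px, px, 3, N) array
#' @return N x 4 matrix of class probabilities
#' @export
predict_crops <- function(object, crops) {
  if (length(dim(crops)) == 3) crops <- array(crops, dim = c(dim(crops), 1))
  for (ch in 1:3) {
    crops[, , ch, ] <- (crops[, , ch, ] - object$stats$mean[ch]) /
      object$stats$sd[ch]
  }
  bf <- backbone_forward(object$backbone, crops, training = FALSE)
  fc <- fc_forward(bf$features, object$clf$W, object$clf$b)
  p <- t(softmax(fc$out))
  colnames(p) <- object$classes
  p
}

#' Dense sliding-window inference over a tissue
#'
#' Slides a window of `window_px` with the given stride over the tissue
#' (edge windows clamped inside; a tissue smaller than the window yields a
#' single centered, white-padded window) and classifies each window
#' independently of its neighbours.
#'
#' @param tissue (H, W, 3) array or a crop from [segment_tissues()]
#' @param classifier a `crop_classifier`
#' @param window_px window size; defaults to the classifier's crop size
#' @param stride step between windows; defaults to `window_px`
#' @return list of class `window_grid`: `probs` (N x 4), `coords`
#'   (data.frame x0, y0, 0-based)
#' @export
classify_windows <- function(tissue, classifier, window_px = NULL,
                             stride = NULL) {
  if (is.list(tissue) && !is.null(tissue$pixels)) tissue <- tissue$pixels
  if (is.null(window_px)) window_px <- classifier$crop_px
  if (is.null(stride)) stride <- window_px
  d <- dim(tissue)
  starts <- function(size) {
    if (size <= window_px) return(1L)
    s <- seq(1L, size - window_px + 1L, by = stride)
    if (s[length(s)] != size - window_px + 1L) {
      s <- c(s, size - window_px + 1L)
    }
    s
  }
  ys <- starts(d[1]); xs <- starts(d[2])
  coords <- expand.grid(y0 = ys - 1L, x0 = xs - 1L)
  n <- nrow(coords)
  wins <- array(1, dim = c(window_px, window_px, 3, n))
  for (i in seq_len(n)) {
    y <- coords$y0[i] + 1L; x <- coords$x0[i] + 1L
    h <- min(window_px, d[1]); w <- min(window_px, d[2])
    wins[seq_len(h), seq_len(w), , i] <-
      tissue[y:(y + h - 1), x:(x + w - 1), , drop = FALSE]
  }
  probs <- predict_crops(classifier, wins)
  structure(list(probs = probs, coords = coords, window_px = window_px,
                 stride = stride, dims = d[1:2]),
            class = "window_grid")
}

#' Heuristic aggregation configuration
#'
#' Per-abnormal-class confidence thresholds and minimum counts of
#' confident windows; class priority is the clinical risk order.
#'
#' @param thresholds named numeric in \[0, 1\] for the three abnormal classes
#' @param min_counts named nonnegative integers for the same classes
#' @return list of class `heuristic_config`
#' @export
heuristic_config <- function(thresholds = c("BE-no-dysplasia" = 0.5,
                                            "BE-with-dysplasia" = 0.5,
                                            "adenocarcinoma" = 0.5),
                             min_counts = c("BE-no-dysplasia" = 1,
                                            "BE-with-dysplasia" = 1,
                                            "adenocarcinoma" = 1)) {
  abn <- setdiff(class_order(), "normal")
  stopifnot(all(abn %in% names(thresholds)), all(abn %in% names(min_counts)),
            all(thresholds >= 0 & thresholds <= 1), all(min_counts >= 0))
  structure(list(thresholds = thresholds[abn], min_counts = min_counts[abn]),
            class = "heuristic_config")
}

#' Aggregate window predictions into a tissue-level class
#'
#' Counts, per abnormal class, the windows whose probability for that
#' class exceeds its threshold; walking from highest to lowest risk, the
#' first class whose confident-window count reaches its minimum count is
#' predicted; otherwise normal.
#'
#' @param window_grid from [classify_windows()]
#' @param heuristic a [heuristic_config()]
#' @return predicted class (character)
#' @export
aggregate_windows <- function(window_grid, heuristic = heuristic_config()) {
  stopifnot(inherits(window_grid, "window_grid"), nrow(window_grid$probs) > 0)
  for (cl in rev(setdiff(class_order(), "normal"))) {
    cnt <- sum(window_grid$probs[, cl] > heuristic$thresholds[[cl]])
    if (cnt >= max(1, heuristic$min_counts[[cl]])) return(cl)
  }
  "normal"
}

#' Grid search for the aggregation heuristic
#'
#' Exhaustively searches per-class thresholds and minimum counts on the
#' validation set, maximizing the unweighted mean F1 over the four
#' classes.  Ties are broken toward lower thresholds (then lower counts),
#' making the search deterministic.
#'
#' @param window_grids list of `window_grid`s for the validation tissues
#' @param labels their reference labels
#' @param thr_grid candidate thresholds
#' @param count_grid candidate minimum counts
#' @return list(config = best [heuristic_config()], score, searched)
#' @export
grid_search_heuristic <- function(window_grids, labels,
                                  thr_grid = c(0.5, 0.7, 0.9),
                                  count_grid = c(1, 2)) {
  stopifnot(length(window_grids) == length(labels),
            length(thr_grid) > 0, length(count_grid) > 0)
  abn <- setdiff(class_order(), "normal")
  per_class <- expand.grid(thr = sort(thr_grid), cnt = sort(count_grid))
  combo_idx <- expand.grid(rep(list(seq_len(nrow(per_class))), length(abn)))
  best <- NULL
  for (r in seq_len(nrow(combo_idx))) {
    thr <- stats::setNames(per_class$thr[unlist(combo_idx[r, ])], abn)
    cnt <- stats::setNames(per_class$cnt[unlist(combo_idx[r, ])], abn)
    hc <- heuristic_config(thr, cnt)
    preds <- vapply(window_grids, aggregate_windows, "", heuristic = hc)
    cm <- confusion_matrix(labels, preds)
    score <- mean(vapply(class_order(),
                         function(cl) unname(one_vs_rest_metrics(cm, cl)["f1"]),
                         0))
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(config = hc, score = score)
    }
  }
  best$searched <- nrow(combo_idx)
  best
}

#' Fit the sliding-window baseline end-to-end
#'
#' Trains the crop classifier on ROI crops from the training slides,
#' computes validation window grids, grid-searches the aggregation
#' heuristic, and returns a baseline model with a `predict` method.
#' Fails loudly when box annotations are missing — this baseline, unlike
#' the attention model, cannot train without them.
#'
#' @param manifest tissue manifest
#' @param boxes lesion-box annotations (required)
#' @param crop_px crop/window size
#' @param epochs crop-classifier epochs
#' @param k backbone feature dimensionality
#' @param val_fraction fraction of slides for heuristic validation
#' @param thr_grid,count_grid heuristic search grids
#' @param seed RNG seed
#' @param data_dir directory for relative image paths
#' @param verbose print progress
#' @return object of class `wsi_baseline`
#' @export
baseline_fit <- function(manifest, boxes, crop_px = 224, epochs = 20,
                         k = 16, val_fraction = 0.25,
                         thr_grid = c(0.5, 0.7, 0.9), count_grid = c(1, 2),
                         seed = 1, data_dir = NULL, verbose = FALSE) {
  if (missing(boxes) || is.null(boxes) || nrow(boxes) == 0) {
    stop("the sliding-window baseline requires lesion bounding-box ",
         "annotations; none were supplied (the attention model needs none)")
  }
  set.seed(seed)
  slides <- unique(manifest$slide_id)
  n_val <- max(1, round(val_fraction * length(slides)))
  val_slides <- if (length(slides) >= 2) sample(slides, n_val) else character(0)
  is_val <- manifest$slide_id %in% val_slides
  crop_set <- make_crop_set(manifest[!is_val, , drop = FALSE], boxes,
                            crop_px = crop_px, seed = seed,
                            data_dir = data_dir)
  clf <- train_crop_classifier(crop_set, epochs = epochs, k = k,
                               seed = seed, verbose = verbose)
  val_manifest <- manifest[is_val, , drop = FALSE]
  heur <- heuristic_config()
  score <- NA_real_
  if (nrow(val_manifest) > 0) {
    grids <- lapply(seq_len(nrow(val_manifest)), function(i) {
      classify_windows(load_manifest_image(val_manifest, i, data_dir), clf)
    })
    gs <- grid_search_heuristic(grids, val_manifest$label, thr_grid,
                                count_grid)
    heur <- gs$config
    score <- gs$score
  }
  structure(list(classifier = clf, heuristic = heur,
                 val_score = score, crop_px = crop_px,
                 classes = class_order(), call = match.call()),
            class = "wsi_baseline")
}

#' @export
print.wsi_baseline <- function(x, ...) {
  cat("Sliding-window baseline (ROI-crop classifier + heuristics)\n")
  cat("  window: ", x$crop_px, " px\n", sep = "")
  cat("  thresholds: ",
      paste(sprintf("%s=%.2f", names(x$heuristic$thresholds),
                    x$heuristic$thresholds), collapse = ", "), "\n")
  if (is.finite(x$val_score)) {
    cat("  validation mean F1: ", sprintf("%.3f", x$val_score), "\n", sep = "")
  }
  invisible(x)
}

#' @export
predict.wsi_baseline <- function(object, newdata, data_dir = NULL,
                                 stride = NULL, ...) {
  images <- coerce_images(newdata, data_dir)
  preds <- vapply(images, function(img) {
    aggregate_windows(classify_windows(img, object$classifier,
                                       stride = stride), object$heuristic)
  }, "")
  factor(preds, levels = object$classes)
}
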