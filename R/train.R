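# Training: initialization scheme, cyclical learning-rate schedule,
# augmentation, and the end-to-end optimization loop.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam from 1e-3 decaying by 0.95
#' per epoch, reset to 1e-4 every 50 epochs over 200 epochs, mini-batches
#' of 2 whole tissue images (assembled by per-image gradient accumulation,
#' since grids differ in shape), random rotation and random isotropic
#' scaling in \[0.8, 1.2\] as augmentation, and only the cross-entropy loss
#' against tissue-level labels — lesion boxes are never consumed.
#'
#' @param lr0 initial learning rate
#' @param decay per-epoch multiplicative decay
#' @param cycle_reset_lr learning rate at the start of each later cycle
#' @param cycle_length epochs per cycle
#' @param total_epochs total training epochs
#' @param batch_size images per optimization step
#' @param scale_range random-scaling factor range
#' @param rotation "right_angle" (multiples of 90 degrees), "continuous",
#'   or "none"
#' @param augment master switch for augmentation
#' @param decay_within_cycle if `TRUE` the 0.95 decay continues inside each
#'   reset cycle; if `FALSE` the rate is held at `cycle_reset_lr`
#' @param val_fraction fraction of slides reserved for validation
#' @param seed seed for all RNG streams (weights, shuffling, dropout,
#'   augmentation)
#' @return list of class `train_config`
#' @export
train_config <- function(lr0 = 1e-3, decay = 0.95, cycle_reset_lr = 1e-4,
                         cycle_length = 50, total_epochs = 200,
                         batch_size = 2, scale_range = c(0.8, 1.2),
                         rotation = c("right_angle", "continuous", "none"),
                         augment = TRUE, decay_within_cycle = TRUE,
                         val_fraction = 0.2, seed = 1) {
  rotation <- match.arg(rotation)
  stopifnot(decay > 0, decay < 1, cycle_length >= 1,
            total_epochs >= 1, batch_size >= 1,
            length(scale_range) == 2, scale_range[1] <= scale_range[2])
  structure(list(lr0 = lr0, decay = decay, cycle_reset_lr = cycle_reset_lr,
                 cycle_length = cycle_length, total_epochs = total_epochs,
                 batch_size = batch_size, scale_range = scale_range,
                 rotation = rotation, augment = augment,
                 decay_within_cycle = decay_within_cycle,
                 val_fraction = val_fraction, seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the cyclical schedule: within the first cycle
#' `lr0 * decay^epoch`; from epoch `cycle_length` on, the rate resets to
#' `cycle_reset_lr` at the start of each cycle and (by default) continues
#' decaying within it: `cycle_reset_lr * decay^(epoch mod cycle_length)`.
#'
#' @param epoch 0-based epoch index in `[0, total_epochs)`
#' @param config a [train_config()]
#' @return learning rate
#' @export
#' @examples
#' lr_schedule(0, train_config())   # 1e-3
#' lr_schedule(50, train_config())  # 1e-4
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 0 | epoch >= config$total_epochs)) {
    stop("epoch out of range [0, ", config$total_epochs, ")")
  }
  ifelse(epoch < config$cycle_length,
         config$lr0 * config$decay^epoch,
         config$cycle_reset_lr *
           if (config$decay_within_cycle) {
             config$decay^(epoch %% config$cycle_length)
           } else 1)
}

# Rotate an (H, W, 3) image by a multiple of 90 degrees (k in 0:3,
# counter-clockwise); exact, no interpolation.
rotate90 <- function(img, k) {
  k <- k %% 4
  if (k == 0) return(img)
  for (i in seq_len(k)) {
    d <- dim(img)
    img <- aperm(img, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  img
}

#' Randomly augment a tissue image
#'
#' One random rotation and one random isotropic scaling with factor drawn
#' uniformly from `scale_range`.  Uses the current RNG stream; with
#' augmentation disabled the image passes through unchanged.
#'
#' @param img (H, W, 3) array
#' @param config a [train_config()]
#' @return augmented image
#' @export
augment_image <- function(img, config = train_config()) {
  if (!config$augment) return(img)
  if (config$rotation == "right_angle") {
    img <- rotate90(img, sample.int(4, 1) - 1)
  } else if (config$rotation == "continuous") {
    ang <- stats::runif(1, 0, 360)
    out <- EBImage::rotate(EBImage::Image(img, colormode = "Color"), ang,
                           bg.col = "white")
    img <- array(EBImage::imageData(out), dim = dim(EBImage::imageData(out)))
  }
  s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
  d <- dim(img)
  resize_rgb(img, max(8, round(d[1] * s)), max(8, round(d[2] * s)))
}

#' Re-initialize all model weights
#'
#' Applies the initialization scheme: He (MSRA) for convolutional filters
#' (including the 3-D attention filters), Glorot for fully connected
#' layers, unit weight and zero bias for batch normalizations, zero for
#' all biases.  Deterministic given the seed.
#'
#' @param model an `attn_model`
#' @param seed optional seed set before drawing
#' @return the re-initialized model
#' @export
initialize_weights <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flat <- model_params(model)
  for (nm in names(flat)) {
    p <- flat[[nm]]
    leaf <- sub(".*\\.", "", nm)
    if (leaf == "W" && is.array(p) && length(dim(p)) == 4) {
      d <- dim(p)
      flat[[nm]] <- init_msra(d[1], d[2], d[3], d[4])
    } else if (leaf == "W" && is.matrix(p)) {
      flat[[nm]] <- init_glorot(nrow(p), ncol(p))
    } else if (leaf == "gamma") {
      flat[[nm]] <- rep(1, length(p))
    } else if (leaf %in% c("b", "beta")) {
      flat[[nm]] <- numeric(length(p))
    } else if (leaf == "run_mean") {
      flat[[nm]] <- numeric(length(p))
    } else if (leaf == "run_var") {
      flat[[nm]] <- rep(1, length(p))
    }
  }
  model_set_params(model, flat)
}

# Load the pixel array for one manifest row; manifests carry either an
# in-memory `image` list-column or an `image_path` column.
load_manifest_image <- function(manifest, i, data_dir = NULL) {
  if (!is.null(manifest[["image"]])) return(manifest[["image"]][[i]])
  path <- manifest[["image_path"]][i]
  if (!is.null(data_dir) && !file.exists(path)) {
    path <- file.path(data_dir, path)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
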