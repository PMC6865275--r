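# Synthetic tissue-image generator.
#
# Generates high-resolution-style RGB tissue images: an elliptical tissue
# region carrying a smooth "normal" texture on a near-white slide
# background, with zero or more rectangular, soft-edged lesion regions
# carrying class-specific procedural textures.  Textures are filtered-noise
# blob processes (base colour + band-limited noise + speckle), so classes
# differ in colour, blob scale and contrast — enough for simple texture
# statistics to separate them, which keeps the learning task solvable while
# making no attempt at photorealistic histology.

#' Default per-class texture parameters
#'
#' Each class has a base RGB colour, a blob scale (pixels per noise knot),
#' a blob amplitude and a per-pixel speckle amplitude.  Risk increases with
#' darker colour, finer blobs and higher contrast, loosely mimicking the
#' denser, more disorganised appearance of dysplastic and malignant tissue
#' in hematoxylin-eosin stains.
#'
#' @return named list of texture parameter lists, one per class
#' @export
default_textures <- function() {
  list(
    "normal" = list(base = c(0.93, 0.78, 0.83), blob_scale = 24,
                    blob_amp = 0.05, speckle = 0.012),
    "BE-no-dysplasia" = list(base = c(0.60, 0.62, 0.86), blob_scale = 14,
                             blob_amp = 0.10, speckle = 0.035),
    "BE-with-dysplasia" = list(base = c(0.55, 0.38, 0.68), blob_scale = 8,
                               blob_amp = 0.14, speckle = 0.06),
    "adenocarcinoma" = list(base = c(0.36, 0.25, 0.42), blob_scale = 5,
                            blob_amp = 0.20, speckle = 0.10)
  )
}

# Band-limited noise field: coarse N(0,1) knots bilinearly upsampled.
noise_field <- function(h, w, scale) {
  ch <- max(2L, ceiling(h / scale))
  cw <- max(2L, ceiling(w / scale))
  coarse <- matrix(stats::rnorm(ch * cw), ch, cw)
  if (ch == h && cw == w) return(coarse)
  resize_matrix(coarse, h, w)
}

# Render one class texture patch of size h x w using the current RNG.
render_texture <- function(h, w, p) {
  nf <- noise_field(h, w, p$blob_scale)
  mix <- c(1, 0.85, 0.92)       # correlated channels, as in stained tissue
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    out[, , ch] <- p$base[ch] + p$blob_amp * mix[ch] * nf +
      p$speckle * stats::rnorm(h * w)
  }
  pmin(pmax(out, 0), 1)
}

#' Specification for one synthetic tissue image
#'
#' @param width,height image size in pixels
#' @param lesions list of lesions, each `list(class, box)` with
#'   `box = c(x_min, y_min, x_max, y_max)` (0-based, half-open, x = column)
#'   and optionally `texture_params` overriding the class default
#' @param background_texture_class texture drawn inside the tissue region
#'   outside any lesion; normal tissue by default
#' @param seed RNG seed making the image fully reproducible
#' @param margin_frac white margin between the tissue ellipse and the frame
#' @param textures per-class texture parameters
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(width, height, lesions = list(),
                           background_texture_class = "normal", seed = 1,
                           margin_frac = 0.04, textures = default_textures()) {
  stopifnot(width >= 8, height >= 8)
  validate_classes(background_texture_class)
  for (les in lesions) {
    validate_classes(les$class)
    b <- les$box
    if (length(b) != 4 || b[1] < 0 || b[2] < 0 ||
        b[3] <= b[1] || b[4] <= b[2] || b[3] > width || b[4] > height) {
      stop("lesion box out of bounds or degenerate: ",
           paste(b, collapse = ", "))
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 lesions = lesions,
                 background_texture_class = background_texture_class,
                 seed = seed, margin_frac = margin_frac, textures = textures),
            class = "synthetic_spec")
}

# Soft-edged rectangular blend weight for a box on an h x w canvas.
box_weight <- function(h, w, box, ramp_frac = 0.12) {
  x0 <- box[1] + 1; y0 <- box[2] + 1; x1 <- box[3]; y1 <- box[4]
  ramp <- max(2, round(ramp_frac * min(x1 - x0 + 1, y1 - y0 + 1)))
  prof <- function(n) {
    r <- min(ramp, floor(n / 2))
    p <- rep(1, n)
    if (r > 0) {
      up <- seq_len(r) / (r + 1)
      p[seq_len(r)] <- up
      p[n + 1 - seq_len(r)] <- up
    }
    p
  }
  wy <- numeric(h); wx <- numeric(w)
  wy[y0:y1] <- prof(y1 - y0 + 1)
  wx[x0:x1] <- prof(x1 - x0 + 1)
  outer(wy, wx)
}

#' Generate one synthetic tissue image
#'
#' Renders the tissue ellipse with the background-class texture, composites
#' each lesion's class texture over its (soft-edged) box, and derives the
#' tissue-level label from the lesion classes by the highest-risk rule.
#' Deterministic: the same spec (including seed) yields pixel-identical
#' output.
#'
#' @param spec a [synthetic_spec()]
#' @return object of class `tissue_image`: list(pixels, label, lesion_boxes,
#'   source_id, tissue_mask)
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  # near-white slide background (all channels >= 0.955 > 240/255)
  pixels <- array(0.975 + 0.02 * (stats::runif(h * w * 3) - 0.5),
                  dim = c(h, w, 3))
  # tissue ellipse
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ay <- (0.5 - spec$margin_frac) * h
  ax <- (0.5 - spec$margin_frac) * w
  yy <- ((seq_len(h) - cy) / ay)^2
  xx <- ((seq_len(w) - cx) / ax)^2
  tissue_mask <- outer(yy, xx, "+") <= 1
  bg <- render_texture(h, w, spec$textures[[spec$background_texture_class]])
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[tissue_mask] <- bg[, , ch][tissue_mask]
    pixels[, , ch] <- plane
  }
  for (les in spec$lesions) {
    p <- les$texture_params
    if (is.null(p)) p <- spec$textures[[les$class]]
    tex <- render_texture(h, w, p)
    wt <- box_weight(h, w, les$box) * tissue_mask
    for (ch in 1:3) {
      pixels[, , ch] <- (1 - wt) * pixels[, , ch] + wt * tex[, , ch]
    }
  }
  boxes <- if (length(spec$lesions) == 0) {
    data.frame(class = character(0), x_min = integer(0), y_min = integer(0),
               x_max = integer(0), y_max = integer(0))
  } else {
    data.frame(class = vapply(spec$lesions, `[[`, "", "class"),
               x_min = vapply(spec$lesions, function(l) l$box[1], 0),
               y_min = vapply(spec$lesions, function(l) l$box[2], 0),
               x_max = vapply(spec$lesions, function(l) l$box[3], 0),
               y_max = vapply(spec$lesions, function(l) l$box[4], 0))
  }
  structure(list(pixels = pixels,
                 label = assign_label(boxes$class),
                 lesion_boxes = boxes,
                 source_id = sprintf("synthetic_seed%s",
                                     format(spec$seed %||% "NA")),
                 tissue_mask = NULL),
            class = "tissue_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel mask of the lesion boxes of a tissue
#' @param boxes data frame with x_min, y_min, x_max, y_max (0-based half-open)
#' @param h,w image dimensions
#' @param classes optional subset of lesion classes to include
#' @return logical (h, w) matrix
#' @export
lesion_pixel_mask <- function(boxes, h, w, classes = NULL) {
  m <- matrix(FALSE, h, w)
  if (!is.null(classes)) boxes <- boxes[boxes$class %in% classes, , drop = FALSE]
  for (i in seq_len(nrow(boxes))) {
    m[(boxes$y_min[i] + 1):boxes$y_max[i],
      (boxes$x_min[i] + 1):boxes$x_max[i]] <- TRUE
  }
  m
}

#' Class frequencies of the esophageal study cohort
#'
#' The 4-class mix observed across 379 tissue images: 195 normal, 80 BE
#' without dysplasia, 46 BE with dysplasia, 58 adenocarcinoma.
#' @return named numeric probabilities summing to 1
#' @export
study_class_mix <- function() {
  stats::setNames(c(195, 80, 46, 58) / 379, class_order())
}

# Draw tissue width/height: "desk" is a fixed 3x4 grid of 492-px cells;
# "paper" draws lognormal sizes matching the observed medians (width 4500,
# IQR 3000-6500; height 5500, IQR 4000-7500).
sample_tissue_size <- function(size_distribution, width, height) {
  if (!is.null(width) && !is.null(height)) {
    return(c(h = as.integer(height), w = as.integer(width)))
  }
  if (size_distribution == "desk") return(c(h = 1476L, w = 1968L))
  sdlog_w <- log(6500 / 3000) / (2 * stats::qnorm(0.75))
  sdlog_h <- log(7500 / 4000) / (2 * stats::qnorm(0.75))
  c(h = as.integer(round(stats::rlnorm(1, log(5500), sdlog_h))),
    w = as.integer(round(stats::rlnorm(1, log(4500), sdlog_w))))
}

# Sample lesion boxes for a tissue of the given label; the primary lesion
# carries the label class, optional extras carry strictly-lower-risk
# abnormal classes so the highest-risk rule reproduces the label.
sample_lesions <- function(label, h, w, lesion_frac = c(0.18, 0.38),
                           p_extra = 0.35) {
  if (label == "normal") return(list())
  draw_box <- function() {
    fw <- stats::runif(1, lesion_frac[1], lesion_frac[2])
    fh <- stats::runif(1, lesion_frac[1], lesion_frac[2])
    cx <- stats::runif(1, 0.22 + fw / 2, 0.78 - fw / 2)
    cy <- stats::runif(1, 0.22 + fh / 2, 0.78 - fh / 2)
    c(floor((cx - fw / 2) * w), floor((cy - fh / 2) * h),
      ceiling((cx + fw / 2) * w), ceiling((cy + fh / 2) * h))
  }
  overlaps <- function(a, b) {
    a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
  }
  lesions <- list(list(class = label, box = draw_box()))
  lower <- class_order()[seq_len(class_rank(label) - 1)]
  lower <- setdiff(lower, "normal")
  if (length(lower) > 0 && stats::runif(1) < p_extra) {
    for (try in 1:20) {
      b <- draw_box()
      if (!any(vapply(lesions, function(l) overlaps(l$box, b), TRUE))) {
        lesions <- c(lesions, list(list(class = sample(lower, 1), box = b)))
        break
      }
    }
  }
  lesions
}

#' Generate a synthetic dataset of tissue images
#'
#' Draws tissue-level labels from `class_mix`, plants lesions consistent
#' with each label (a lesion of the label class, occasionally plus a
#' lower-risk lesion), renders each image, and either keeps the images
#' in memory (`image` list-column) or writes PNGs plus a label manifest and
#' a box-annotation CSV to `out_dir`.
#'
#' @param n number of tissue images
#' @param out_dir optional output directory; when given, images are written
#'   as PNG and the manifest gains an `image_path` column
#' @param class_mix per-class probabilities; defaults to the study cohort mix
#' @param size_distribution "desk" (fixed 1476 x 1968) or "paper"
#'   (lognormal around the observed tissue medians); ignored when `width`
#'   and `height` are given
#' @param width,height fixed image size override (pixels)
#' @param seed RNG seed; the whole dataset is reproducible from it
#' @param lesion_frac range of lesion extent as a fraction of each dimension
#' @return list with `manifest` (data.frame: tissue_id, slide_id, label and
#'   image or image_path) and `boxes` (data.frame of lesion boxes)
#' @export
generate_dataset <- function(n, out_dir = NULL, class_mix = study_class_mix(),
                             size_distribution = c("desk", "paper"),
                             width = NULL, height = NULL, seed = 1,
                             lesion_frac = c(0.18, 0.38)) {
  stopifnot(n >= 1)
  size_distribution <- match.arg(size_distribution)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  validate_classes(names(class_mix))
  set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  labels <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  rows <- vector("list", n)
  box_rows <- vector("list", n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    sz <- sample_tissue_size(size_distribution, width, height)
    lesions <- sample_lesions(labels[i], sz["h"], sz["w"], lesion_frac)
    spec <- synthetic_spec(width = sz["w"], height = sz["h"],
                           lesions = lesions,
                           seed = sample.int(.Machine$integer.max, 1))
    ti <- generate_tissue_image(spec)
    tissue_id <- sprintf("tissue_%04d", i)
    slide_id <- sprintf("slide_%04d", i)
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(tissue_id, ".png"))
      png::writePNG(ti$pixels, path)
    } else {
      images[[i]] <- ti$pixels
    }
    rows[[i]] <- data.frame(image_path = path, tissue_id = tissue_id,
                            slide_id = slide_id, label = ti$label)
    if (nrow(ti$lesion_boxes) > 0) {
      box_rows[[i]] <- cbind(data.frame(image_path = path,
                                        tissue_id = tissue_id),
                             ti$lesion_boxes)
    }
  }
  manifest <- do.call(rbind, rows)
  if (is.null(out_dir)) manifest$image <- images
  boxes <- if (any(!vapply(box_rows, is.null, TRUE))) {
    do.call(rbind, box_rows[!vapply(box_rows, is.null, TRUE)])
  } else {
    data.frame(image_path = character(0), tissue_id = character(0),
               class = character(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0))
  }
  rownames(manifest) <- NULL
  rownames(boxes) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(boxes, file.path(out_dir, "boxes.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, boxes = boxes)
}

#' Compose a synthetic slide holding several tissues
#'
#' Lays `n_tissues` synthetic tissue images horizontally on one near-white
#' canvas with white gutters, emulating a whole-slide scan that covers
#' multiple pieces of tissue, for exercising tissue separation.
#'
#' @param n_tissues number of tissue pieces
#' @param tissue_width,tissue_height per-tissue size in pixels
#' @param labels optional vector of labels (default all normal)
#' @param seed RNG seed
#' @param gap white gutter between tissues, pixels
#' @return list(pixels, tissues): the slide image and the individual
#'   `tissue_image` objects with their horizontal offsets
#' @export
generate_slide <- function(n_tissues = 2, tissue_width = 240,
                           tissue_height = 200, labels = NULL, seed = 1,
                           gap = 40) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep("normal", n_tissues)
  h <- tissue_height + 2 * gap
  w <- n_tissues * tissue_width + (n_tissues + 1) * gap
  slide <- array(0.975 + 0.02 * (stats::runif(h * w * 3) - 0.5),
                 dim = c(h, w, 3))
  tissues <- vector("list", n_tissues)
  for (i in seq_len(n_tissues)) {
    lesions <- sample_lesions(labels[i], tissue_height, tissue_width)
    spec <- synthetic_spec(width = tissue_width, height = tissue_height,
                           lesions = lesions,
                           seed = sample.int(.Machine$integer.max, 1))
    ti <- generate_tissue_image(spec)
    x0 <- gap + (i - 1) * (tissue_width + gap)
    slide[(gap + 1):(gap + tissue_height),
          (x0 + 1):(x0 + tissue_width), ] <- ti$pixels
    ti$offset <- c(x = x0, y = gap)
    tissues[[i]] <- ti
  }
  list(pixels = slide, tissues = tissues)
}
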