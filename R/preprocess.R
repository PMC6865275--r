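# Preprocessing: background removal and tissue separation, grid tiling,
# and channel normalization.
#
# Conventions used repo-wide: images are (H, W, 3) double arrays in [0, 1];
# boxes are 0-based, half-open (x_min, y_min, x_max, y_max) with x = column,
# y = row; grids are indexed row-major.

# Separable bilinear interpolation matrix mapping n_in samples to n_out.
# Output pixel centers are sampled at (i - 0.5) * n_in / n_out + 0.5 on the
# input pixel grid (edge-clamped), so resizing to the same size is exact
# identity and constants are preserved.
bilinear_matrix <- function(n_out, n_in) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  lo <- pmin(pmax(floor(pos), 1), n_in)
  hi <- pmin(lo + 1, n_in)
  w <- pos - lo
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), lo)] <- 1 - w
  M[cbind(seq_len(n_out), hi)] <- M[cbind(seq_len(n_out), hi)] + w
  M
}

#' Resize a matrix with bilinear interpolation
#' @keywords internal
resize_matrix <- function(m, out_h, out_w) {
  bilinear_matrix(out_h, nrow(m)) %*% m %*% t(bilinear_matrix(out_w, ncol(m)))
}

#' Resize an (H, W, 3) image with bilinear interpolation
#'
#' Separable interpolation as two matrix products per channel (BLAS-backed).
#' @keywords internal
resize_rgb <- function(img, out_h, out_w) {
  Ry <- bilinear_matrix(out_h, dim(img)[1])
  Rx <- t(bilinear_matrix(out_w, dim(img)[2]))
  out <- array(0, dim = c(out_h, out_w, 3))
  for (ch in 1:3) out[, , ch] <- Ry %*% img[, , ch] %*% Rx
  out
}

#' Separate a slide image into single-tissue subimages
#'
#' Removes the white background and extracts one tight crop per connected
#' tissue component, so each subimage covers a single piece of tissue.
#' A pixel is background when all three channels are at or above
#' `bg_threshold`; connected components (8-connectivity) smaller than
#' `min_area_frac` of the image are discarded as debris.  Every crop keeps
#' provenance to its source slide so train/test splits can keep tissues from
#' one slide together.
#'
#' @param slide (H, W, 3) array in \[0, 1\]
#' @param slide_id identifier recorded on each crop
#' @param bg_threshold background threshold on \[0, 1\]; default 240/255
#' @param min_area_frac minimum component area as a fraction of image area
#' @return list of tissue crops: each `list(pixels, bbox, slide_id, tissue_id)`
#'   where `bbox = c(x_min, y_min, x_max, y_max)` locates the crop on the
#'   slide (0-based, half-open)
#' @export
segment_tissues <- function(slide, slide_id = "slide", bg_threshold = 240 / 255,
                            min_area_frac = 0.001) {
  stopifnot(length(dim(slide)) == 3, dim(slide)[3] == 3)
  mask <- !(slide[, , 1] >= bg_threshold &
            slide[, , 2] >= bg_threshold &
            slide[, , 3] >= bg_threshold)
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_frac * length(mask))
  out <- list()
  for (i in seq_along(keep)) {
    comp <- lab == keep[i]
    rows <- which(rowSums(comp) > 0)
    cols <- which(colSums(comp) > 0)
    r0 <- min(rows); r1 <- max(rows)
    c0 <- min(cols); c1 <- max(cols)
    out[[i]] <- list(
      pixels = slide[r0:r1, c0:c1, , drop = FALSE],
      bbox = c(x_min = c0 - 1, y_min = r0 - 1, x_max = c1, y_max = r1),
      slide_id = slide_id,
      tissue_id = sprintf("%s_t%02d", slide_id, i)
    )
  }
  out
}

#' Tile a tissue image into a grid of fixed-size cells
#'
#' Pads the image with white to the next multiple of `cell_px` in each
#' dimension (so no tissue pixel is discarded), splits it into
#' `r = ceil(H / cell_px)` by `c = ceil(W / cell_px)` cells in row-major
#' order, and bilinearly resizes each cell to `out_px`.  The defaults are
#' 492-pixel cells resized to 224 pixels, the geometry used for 20x scans;
#' both are tunable for scaled-down work.
#'
#' @param tissue (H, W, 3) array, or a crop from [segment_tissues()]
#' @param cell_px grid cell size in source pixels
#' @param out_px output cell size after resizing
#' @return list with `shape = c(r, c)`, `cells` (out_px, out_px, 3, r*c)
#'   array in row-major cell order, `cell_px`, and `dims` (original H, W)
#' @export
tile_grid <- function(tissue, cell_px = 492, out_px = 224) {
  if (is.list(tissue) && !is.null(tissue$pixels)) tissue <- tissue$pixels
  d <- dim(tissue)
  stopifnot(length(d) == 3, d[3] == 3, d[1] >= 1, d[2] >= 1)
  r <- ceiling(d[1] / cell_px)
  cc <- ceiling(d[2] / cell_px)
  padded <- array(1, dim = c(r * cell_px, cc * cell_px, 3))
  padded[seq_len(d[1]), seq_len(d[2]), ] <- tissue
  # resample the whole padded image once and split: one bilinear pass over
  # the image is equivalent to per-cell resizing up to interpolation at
  # cell boundaries, and far cheaper for large grids
  small <- if (cell_px == out_px) padded else
    resize_rgb(padded, r * out_px, cc * out_px)
  cells <- array(0, dim = c(out_px, out_px, 3, r * cc))
  n <- 0L
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      n <- n + 1L
      cells[, , , n] <- small[((i - 1) * out_px + 1):(i * out_px),
                              ((j - 1) * out_px + 1):(j * out_px), ,
                              drop = FALSE]
    }
  }
  list(shape = c(r = r, c = cc), cells = cells, cell_px = cell_px,
       out_px = out_px, dims = d[1:2])
}

# Reassemble the padded image from unresized cells; used to verify that
# tiling is lossless up to padding.
untile_grid <- function(cells, shape, cell_px) {
  r <- unname(shape[1]); cc <- unname(shape[2])
  out <- array(0, dim = c(r * cell_px, cc * cell_px, 3))
  n <- 0L
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      n <- n + 1L
      out[((i - 1) * cell_px + 1):(i * cell_px),
          ((j - 1) * cell_px + 1):(j * cell_px), ] <- cells[, , , n]
    }
  }
  out
}

#' Per-channel pixel statistics over a set of training tissues
#'
#' Pools every pixel of every training tissue and returns the per-channel
#' mean and standard deviation used to normalize model inputs.  Statistics
#' must be computed on the training set only.  A degenerate (zero) SD is
#' floored at `sd_floor` with a warning.
#'
#' @param images list of (H, W, 3) arrays (sizes may differ)
#' @param sd_floor lower bound applied to each channel SD
#' @return object of class `channel_stats`: list(mean, sd), each length 3
#' @export
compute_normalization_stats <- function(images, sd_floor = 1e-6) {
  if (length(images) == 0) stop("no training tissues supplied")
  n <- 0
  s <- numeric(3)
  ss <- numeric(3)
  for (img in images) {
    if (is.list(img) && !is.null(img$pixels)) img <- img$pixels
    d <- dim(img)
    m <- matrix(img, nrow = d[1] * d[2])
    n <- n + d[1] * d[2]
    s <- s + colSums(m)
    ss <- ss + colSums(m^2)
  }
  mu <- s / n
  va <- pmax(ss / n - mu^2, 0)
  sd <- sqrt(va)
  if (any(sd < sd_floor)) {
    warning("degenerate channel SD floored at ", sd_floor)
    sd <- pmax(sd, sd_floor)
  }
  structure(list(mean = mu, sd = sd, n_pixels = n), class = "channel_stats")
}

#' Normalize grid cells by channel statistics
#'
#' @param cells (H, W, 3, N) array (or the list from [tile_grid()])
#' @param stats a `channel_stats` object
#' @return array of the same shape, per channel `(x - mean) / sd`
#' @export
normalize_cells <- function(cells, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  if (any(stats$sd <= 0)) stop("channel SD must be positive")
  tiled <- NULL
  if (is.list(cells) && !is.null(cells$cells)) {
    tiled <- cells
    cells <- cells$cells
  }
  for (ch in 1:3) {
    cells[, , ch, ] <- (cells[, , ch, ] - stats$mean[ch]) / stats$sd[ch]
  }
  if (!is.null(tiled)) {
    tiled$cells <- cells
    return(tiled)
  }
  cells
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("Channel statistics over", x$n_pixels, "pixels\n")
  cat("  mean:", paste(sprintf("%.4f", x$mean), collapse = " "), "\n")
  cat("  sd:  ", paste(sprintf("%.4f", x$sd), collapse = " "), "\n")
  invisible(x)
}

#' Persist / restore channel statistics as JSON
#' @rdname compute_normalization_stats
#' @param stats a `channel_stats` object
#' @param path JSON file path
#' @export
write_channel_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname compute_normalization_stats
#' @export
read_channel_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                 n_pixels = x$n_pixels), class = "channel_stats")
}
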