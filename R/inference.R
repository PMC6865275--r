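# Attention-map rendering, enrichment scoring, and head selection.

#' Render an attention head at tissue resolution
#'
#' Divides the map by its maximum (so the maximum value is exactly 1,
#' unless the map is all zero, which yields an all-zero render with a
#' warning) and upsamples it from grid to pixel resolution.  Each grid cell
#' maps to the `cell_px` x `cell_px` block of the (padded) tissue it was
#' tiled from; the render is cropped to the tissue dimensions.
#'
#' @param alpha_head r x c matrix of attention weights
#' @param dims tissue dimensions `c(H, W)`
#' @param cell_px grid cell size used at tiling time
#' @param method "nearest" (blocky, exact cell boundaries) or "bilinear"
#' @return H x W matrix in \[0, 1\] of class `attention_render`
#' @export
render_attention <- function(alpha_head, dims, cell_px = 492,
                             method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(alpha_head), all(alpha_head >= 0))
  mx <- max(alpha_head)
  if (mx == 0) {
    warning("all-zero attention map; returning an all-zero render")
  } else {
    alpha_head <- alpha_head / mx
  }
  if (method == "nearest") {
    up <- kronecker(alpha_head, matrix(1, cell_px, cell_px))
  } else {
    up <- resize_matrix(alpha_head, nrow(alpha_head) * cell_px,
                        ncol(alpha_head) * cell_px)
    up <- pmin(pmax(up, 0), 1)
  }
  structure(up[seq_len(dims[1]), seq_len(dims[2]), drop = FALSE],
            class = c("attention_render", "matrix", "array"))
}

#' Attention enrichment inside a lesion mask
#'
#' The ratio of attention mass falling inside the mask to the mask's area
#' fraction of the grid.  Uniform attention scores exactly 1 for any mask;
#' values above 1 mean the head concentrates on the masked cells.
#'
#' @param alpha_head r x c attention matrix (sums to 1)
#' @param mask r x c logical matrix with at least one positive cell
#' @return enrichment ratio (1 = no enrichment)
#' @export
attention_enrichment <- function(alpha_head, mask) {
  stopifnot(all(dim(alpha_head) == dim(mask)))
  if (!any(mask)) stop("empty lesion mask")
  inside <- sum(alpha_head[mask])
  area_frac <- sum(mask) / length(mask)
  (inside / sum(alpha_head)) / area_frac
}

#' Grid-resolution lesion mask from pixel boxes
#'
#' Marks a grid cell positive when its overlap with the lesion boxes covers
#' at least `min_overlap` of the smaller of (cell area, total box area) —
#' the min() makes lesions smaller than half a cell still register in the
#' cell that contains them.
#'
#' @param boxes data frame of lesion boxes (0-based half-open pixel coords)
#' @param dims tissue dimensions `c(H, W)`
#' @param cell_px grid cell size
#' @param classes optional subset of lesion classes
#' @param min_overlap overlap fraction threshold
#' @return r x c logical matrix
#' @export
lesion_grid_mask <- function(boxes, dims, cell_px = 492, classes = NULL,
                             min_overlap = 0.5) {
  if (!is.null(classes)) boxes <- boxes[boxes$class %in% classes, , drop = FALSE]
  r <- ceiling(dims[1] / cell_px)
  cc <- ceiling(dims[2] / cell_px)
  m <- matrix(FALSE, r, cc)
  if (nrow(boxes) == 0) return(m)
  total_box_area <- sum((boxes$x_max - boxes$x_min) *
                        (boxes$y_max - boxes$y_min))
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      cy0 <- (i - 1) * cell_px; cy1 <- i * cell_px
      cx0 <- (j - 1) * cell_px; cx1 <- j * cell_px
      ov <- 0
      for (b in seq_len(nrow(boxes))) {
        ox <- max(0, min(cx1, boxes$x_max[b]) - max(cx0, boxes$x_min[b]))
        oy <- max(0, min(cy1, boxes$y_max[b]) - max(cy0, boxes$y_min[b]))
        ov <- ov + ox * oy
      }
      denom <- min(cell_px^2, total_box_area)
      m[i, j] <- ov >= min_overlap * denom
    }
  }
  m
}

#' Select the attention head most associated with a class
#'
#' Two selection rules are available.  The static rule (no `attention`
#' argument) returns the head whose block of classifier weights carries
#' the largest absolute mass into the class logit — cheap, data-free, and
#' invariant to rescaling all weights by a positive constant.  The
#' data-driven rule takes per-tissue attention results (from
#' `predict(type = "attention")`) and returns the head whose additive
#' contribution to the class logit, `c_f = w_f' z_f`, is most correlated
#' with that logit across tissues — i.e. the head that actually drives the
#' class decision.  Weight magnitude can mislead when a head carries
#' strong *negative* evidence (for instance a head attending normal
#' background), so the data-driven rule is preferred whenever predictions
#' are at hand.
#'
#' @param object a fitted `wsi_attention` or an `attn_model`
#' @param class a class name or index
#' @param attention optional list of per-tissue results from
#'   `predict(type = "attention")` used for the data-driven rule
#' @return head index in `[1, F]`
#' @export
select_class_head <- function(object, class, attention = NULL) {
  model <- if (inherits(object, "wsi_attention")) object$model else object
  if (is.character(class)) class <- match(class, model$classes)
  stopifnot(!is.na(class))
  k <- model$backbone$k
  Fh <- model$config$n_filters
  w <- model$clf$W[, class]
  if (is.null(attention) || length(attention) < 3) {
    mass <- vapply(seq_len(Fh), function(f) {
      sum(abs(w[((f - 1) * k + 1):(f * k)]))
    }, 0)
    return(which.max(mass))
  }
  contrib <- vapply(attention, function(r) {
    vapply(seq_len(Fh), function(f) {
      blk <- ((f - 1) * k + 1):(f * k)
      sum(w[blk] * r$z[blk])
    }, 0)
  }, numeric(Fh))                         # F x n_tissues
  logit <- colSums(contrib) + model$clf$b[class]
  score <- suppressWarnings(apply(contrib, 1, stats::cor, y = logit))
  score[!is.finite(score)] <- -Inf
  which.max(score)
}

#' Attention maps for a set of tissues
#'
#' Convenience wrapper around `predict(type = "attention")` that also
#' computes, per tissue, the enrichment of the predicted class's head
#' inside that class's lesion mask (when boxes are supplied).
#'
#' @param object a fitted `wsi_attention`
#' @param newdata manifest / images as in [predict.wsi_attention()]
#' @param boxes optional lesion-box data frame with a `tissue_id` column
#' @param target_class class whose lesions are scored (default
#'   adenocarcinoma, the highest-risk class)
#' @param data_dir directory for relative image paths
#' @return list per tissue: `class`, `probs`, `alpha`, `shape`, and
#'   `enrichment` (NA when no mask is available)
#' @export
attention_maps <- function(object, newdata, boxes = NULL,
                           target_class = "adenocarcinoma",
                           data_dir = NULL) {
  res <- predict(object, newdata, type = "attention", data_dir = data_dir)
  if (is.null(boxes)) return(res)
  head_idx <- select_class_head(object, target_class, attention = res)
  ids <- if (is.data.frame(newdata)) newdata$tissue_id else
    seq_along(res)
  images <- coerce_images(newdata, data_dir)
  for (i in seq_along(res)) {
    b <- boxes[boxes$tissue_id == ids[i] & boxes$class == target_class, ,
               drop = FALSE]
    res[[i]]$enrichment <- NA_real_
    if (nrow(b) > 0) {
      m <- lesion_grid_mask(b, dim(images[[i]])[1:2], object$cell_px)
      if (any(m)) {
        res[[i]]$enrichment <- attention_enrichment(res[[i]]$alpha[head_idx, , ],
                                                    m)
      }
    }
  }
  res
}
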