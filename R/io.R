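# Manifest and annotation IO.

#' Read / write a tissue label manifest
#'
#' Manifests are CSV with columns `image_path`, `tissue_id`, `slide_id`,
#' `label`; box annotation files are CSV with `image_path`, `tissue_id`,
#' `class`, `x_min`, `y_min`, `x_max`, `y_max` (0-based, half-open).
#'
#' @param path CSV file
#' @return data frame
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue_id", "slide_id", "label")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  validate_classes(m$label)
  m
}

#' @rdname read_manifest
#' @param manifest data frame to write
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest[, setdiff(names(manifest), "image"), drop = FALSE]
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
read_boxes <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue_id", "class", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(b))
  if (length(miss) > 0) {
    stop("box file is missing column(s): ", paste(miss, collapse = ", "))
  }
  validate_classes(b$class)
  b
}

#' Save / load a fitted model as plain JSON
#'
#' Serializes all weights, configuration and channel statistics; arrays are
#' stored with their dimensions so the round trip is exact to double
#' precision printed with 17 significant digits.
#'
#' @param object a `wsi_attention` fit
#' @param path JSON file
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "wsi_attention"))
  flat <- model_params(object$model)
  payload <- list(
    params = lapply(flat, function(p) {
      list(dim = dim(p) %||% length(p), data = as.vector(p))
    }),
    config = unclass(object$model$config),
    backbone = list(name = object$model$backbone$name,
                    k = object$model$backbone$k,
                    width = object$model$backbone$width,
                    widths = object$model$backbone$widths,
                    input_px = object$model$backbone$input_px,
                    frozen = object$model$backbone$frozen),
    stats = unclass(object$stats),
    cell_px = object$cell_px, out_px = object$out_px,
    classes = object$classes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns a `wsi_attention` object ready for
#'   [predict.wsi_attention()] (its training log is empty)
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bb <- if (x$backbone$name == "cnn") {
    backbone_cnn(k = x$backbone$k, width = x$backbone$width,
                 input_px = x$backbone$input_px)
  } else {
    backbone_resnet(widths = x$backbone$widths,
                    input_px = x$backbone$input_px)
  }
  bb$frozen <- as.character(x$backbone$frozen)
  cfg <- attention_config(n_filters = x$config$n_filters,
                          kernel = x$config$kernel,
                          dropout_p = x$config$dropout_p)
  model <- new_attn_model(bb, cfg, classes = as.character(x$classes))
  flat <- lapply(x$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1) array(v, dim = as.integer(p$dim)) else v
  })
  # matrices (2-D) must stay matrices for the classifier layer
  for (nm in names(flat)) {
    if (length(x$params[[nm]]$dim) == 2) {
      flat[[nm]] <- matrix(flat[[nm]], nrow = x$params[[nm]]$dim[1])
    }
  }
  model <- model_set_params(model, flat)
  structure(list(model = model,
                 stats = structure(list(mean = as.numeric(x$stats$mean),
                                        sd = as.numeric(x$stats$sd),
                                        n_pixels = x$stats$n_pixels),
                                   class = "channel_stats"),
                 log = NULL, config = NULL, classes = model$classes,
                 cell_px = x$cell_px, out_px = x$out_px,
                 split = NULL, best_val_acc = NA_real_,
                 call = NULL),
            class = "wsi_attention")
}
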