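#' @export
print.glandnet <- function(x, ...) {
  sp <- x$spec
  cat("Interpolation-pooling gland segmentation network\n")
  cat(sprintf("  input: %dx%dx%d, base channels %d, %s\n", sp$input_size,
              sp$input_size, sp$input_channels, sp$base_channels,
              if (isTRUE(x$fitted)) "fitted" else "not fitted"))
  cat(sprintf("  parameters: %d\n", .n_params(x)))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: val loss %.5f, val F1 %.4f\n",
                last$epoch, last$val_loss, last$val_f1))
  }
  invisible(x)
}

#' @export
summary.glandnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (per epoch):\n")
    print(object$history, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.glandnet <- function(object, ...) object$params

#' Plot training history
#'
#' Two panels: training/validation loss per epoch, and validation F1.
#' @param x a fitted \code{"glandnet"}.
#' @param ... ignored.
#' @export
plot.glandnet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss", main = "Loss")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::plot(h$epoch, h$val_f1, type = "l", col = "forestgreen",
                 xlab = "epoch", ylab = "F1", ylim = c(0, 1),
                 main = "Validation F1")
  invisible(x)
}

#' Segment and count glands in a full leaf image
#'
#' Runs the complete inference chain: the image is decomposed into
#' context-expanded tiles, each tile passes through the network, the
#' rectified responses are thresholded, the margins are trimmed and the
#' cores stitched back into a full-size mask, which is then post-filtered
#' and counted.
#'
#' @param object a fitted \code{"glandnet"}.
#' @param image an H x W x 3 array in \[0, 1\] (any size >= the tile
#'   core; sides need not divide the core size).
#' @param tau binarisation threshold; defaults to the threshold used
#'   during training validation (0.5), falling back to the spec's.
#' @param filter a [filter_config()] for the counting step.
#' @param tile_size,context_size tiling geometry (defaults 100/120).
#' @param ... ignored.
#' @return an object of class \code{"glandnet_prediction"}: \code{mask}
#'   (stitched 0/1 matrix, same size as the image), \code{count},
#'   \code{regions} (filtered \code{"region_set"}), \code{grid},
#'   \code{tau}.
#' @export
predict.glandnet <- function(object, image, tau = NULL,
                             filter = filter_config(),
                             tile_size = 100L, context_size = NULL, ...) {
  stopifnot(inherits(object, "glandnet"))
  if (!(is.array(image) && length(dim(image)) == 3L))
    stop("image must be an H x W x 3 array")
  if (is.null(context_size)) context_size <- object$spec$input_size
  if (is.null(tau))
    tau <- if (!is.null(object$control)) object$control$tau else object$spec$tau
  grid <- tile_grid(dim(image)[2], dim(image)[1], tile_size, context_size)
  tiles <- crop_tiles(image, grid)
  masks <- lapply(tiles, function(tl)
    binarize(net_forward(object, tl), tau))
  full <- stitch_tiles(masks, grid)
  regions <- filter_regions(
    label_components(morphological_close(full, filter$closing_radius),
                     filter$connectivity), filter)
  structure(list(mask = full, count = nrow(regions$regions),
                 regions = regions, grid = grid, tau = tau),
            class = "glandnet_prediction")
}

#' @export
print.glandnet_prediction <- function(x, ...) {
  cat(sprintf("Gland prediction: %d glands in a %dx%d px image (tau %.2f)\n",
              x$count, x$grid$width, x$grid$height, x$tau))
  invisible(x)
}

#' Save a model checkpoint as JSON
#'
#' Stores the architecture spec, all parameters, batch-norm running
#' statistics and the training history in a plain-text JSON file at full
#' numeric precision, so a reloaded model reproduces validation metrics
#' exactly.
#'
#' @param object a \code{"glandnet"}.
#' @param path output .json file.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "glandnet"))
  payload <- list(
    spec = unclass(object$spec),
    params = lapply(object$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    running = object$running,
    history = object$history,
    control = if (is.null(object$control)) NULL else unclass(object$control),
    fitted = object$fitted, seed = object$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path .json checkpoint.
#' @return a \code{"glandnet"} model.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  spec <- payload$spec
  spec$out_channels <- as.integer(spec$out_channels)
  class(spec) <- "glandnet_spec"
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  control <- payload$control
  if (!is.null(control)) class(control) <- "glandnet_control"
  history <- payload$history
  if (!is.null(history)) history <- as.data.frame(history)
  structure(list(spec = spec, params = params,
                 running = lapply(payload$running, as.numeric),
                 history = history, control = control,
                 fitted = isTRUE(payload$fitted),
                 seed = payload$seed),
            class = "glandnet")
}
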