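#' Tile decomposition of a full image
#'
#' Splits an image into non-overlapping square cores (default 100 px, the
#' unit at which gland densities are defined) and, for inference, a
#' context window around each core (default 120 px, i.e. a 10 px margin on
#' every side). Predicting on the enlarged window and trimming the margin
#' back suppresses the edge artefacts that otherwise appear along stitch
#' seams. Images whose sides are not multiples of the core size are
#' reflection-padded on the right/bottom to the next multiple; the
#' stitched result is cropped back to the original size.
#'
#' @param width,height image size in px.
#' @param tile_size core size in px (default 100).
#' @param context_size context window size in px (default 120); the
#'   difference with \code{tile_size} must be even and non-negative.
#' @return an object of class \code{"tile_grid"}: image and padded sizes,
#'   margin, and a data frame \code{tiles} with one row per tile (grid
#'   row/col and the 0-based core offset in the padded image).
#' @export
tile_grid <- function(width, height, tile_size = 100L, context_size = 120L) {
  width <- as.integer(width); height <- as.integer(height)
  tile_size <- as.integer(tile_size)
  context_size <- as.integer(context_size)
  if (width < tile_size || height < tile_size)
    stop("image (", width, "x", height, ") smaller than tile size ",
         tile_size)
  if (context_size < tile_size || (context_size - tile_size) %% 2L != 0L)
    stop("context_size - tile_size must be even and >= 0")
  margin <- (context_size - tile_size) %/% 2L
  pw <- as.integer(ceiling(width / tile_size) * tile_size)
  ph <- as.integer(ceiling(height / tile_size) * tile_size)
  nrow_g <- ph %/% tile_size
  ncol_g <- pw %/% tile_size
  tiles <- expand.grid(col = seq_len(ncol_g), row = seq_len(nrow_g))
  tiles <- tiles[order(tiles$row, tiles$col), c("row", "col")]
  tiles$core_y0 <- (tiles$row - 1L) * tile_size
  tiles$core_x0 <- (tiles$col - 1L) * tile_size
  rownames(tiles) <- NULL
  structure(list(width = width, height = height,
                 padded_width = pw, padded_height = ph,
                 tile_size = tile_size, context_size = context_size,
                 margin = margin, nrow = nrow_g, ncol = ncol_g,
                 tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "Tile grid: %dx%d image -> %d tiles (%d x %d cores of %d px, %d px context, %d px margin)\n",
    x$width, x$height, nrow(x$tiles), x$nrow, x$ncol, x$tile_size,
    x$context_size, x$margin))
  invisible(x)
}

# symmetric (mirror) padding of a 2-D matrix or H x W x C array
.pad_reflect <- function(img, top, bottom, left, right) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (top > H || bottom > H || left > W || right > W)
    stop("reflection padding wider than the image")
  ri <- c(rev(seq_len(top)), seq_len(H), H + 1L - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(W), W + 1L - seq_len(right))
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

#' Crop context tiles from an image
#'
#' @param image matrix (mask) or H x W x C array (RGB), dimensions
#'   matching the grid.
#' @param grid a [tile_grid()].
#' @return a list with one context-sized tile per grid cell, in the row
#'   order of \code{grid$tiles}. Border context is obtained by mirror
#'   padding.
#' @export
crop_tiles <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- dim(image)
  if (is.null(d) || d[1] != grid$height || d[2] != grid$width)
    stop("image dimensions do not match the grid")
  m <- grid$margin
  padded <- .pad_reflect(image,
                         top = m, bottom = m + grid$padded_height - grid$height,
                         left = m, right = m + grid$padded_width - grid$width)
  cs <- grid$context_size
  lapply(seq_len(nrow(grid$tiles)), function(k) {
    y0 <- grid$tiles$core_y0[k]   # 0-based in padded image; context starts
    x0 <- grid$tiles$core_x0[k]   # at the same index because of the pad
    ri <- (y0 + 1L):(y0 + cs)
    ci <- (x0 + 1L):(x0 + cs)
    if (length(d) == 2L) padded[ri, ci, drop = FALSE]
    else padded[ri, ci, , drop = FALSE]
  })
}

#' Stitch predicted tile masks back into a full mask
#'
#' Discards the margin of each context-sized prediction and places the
#' central core at its grid position; every output pixel is written
#' exactly once. \code{stitch_tiles(crop_tiles(m, g), g)} reproduces
#' \code{m} bit-exactly.
#'
#' @param tile_masks list of context-sized matrices, one per grid cell, in
#'   the order of \code{grid$tiles}.
#' @param grid a [tile_grid()].
#' @return a matrix with the original image dimensions.
#' @export
stitch_tiles <- function(tile_masks, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tile_masks) != nrow(grid$tiles))
    stop("expected ", nrow(grid$tiles), " tiles, got ", length(tile_masks))
  m <- grid$margin
  ts <- grid$tile_size
  out <- matrix(tile_masks[[1]][1] * 0L, grid$padded_height,
                grid$padded_width)
  for (k in seq_len(nrow(grid$tiles))) {
    tm <- tile_masks[[k]]
    if (is.null(dim(tm)) || dim(tm)[1] != grid$context_size ||
        dim(tm)[2] != grid$context_size)
      stop("tile ", k, " is not ", grid$context_size, "x",
           grid$context_size)
    core <- tm[(m + 1L):(m + ts), (m + 1L):(m + ts)]
    y0 <- grid$tiles$core_y0[k]
    x0 <- grid$tiles$core_x0[k]
    out[(y0 + 1L):(y0 + ts), (x0 + 1L):(x0 + ts)] <- core
  }
  out[seq_len(grid$height), seq_len(grid$width), drop = FALSE]
}
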