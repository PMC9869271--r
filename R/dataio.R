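#' Read an RGB image (PNG or BMP)
#'
#' @param path file ending in .png or .bmp (24-bit uncompressed BMP, the
#'   camera's native format). Grayscale PNGs are expanded to 3 channels;
#'   an alpha channel is dropped.
#' @return an H x W x 3 array with values in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    img
  } else if (ext == "bmp") {
    read_bmp(path)
  } else {
    stop("unsupported image format: .", ext, " (use .png or .bmp)")
  }
}

#' Write an RGB image (PNG or BMP)
#' @param img H x W x 3 array in \[0, 1\].
#' @param path output file ending in .png or .bmp.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext == "bmp") write_bmp(img, path)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Minimal 24-bit uncompressed BMP reader
#' @param path BMP file (BI_RGB, 24 bits per pixel).
#' @return an H x W x 3 array in \[0, 1\].
#' @export
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4dL)))
    stop("not a BMP file: ", path)
  readBin(con, "integer", 2, size = 4)            # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)            # header size
  W <- readBin(con, "integer", 1, size = 4)
  Hraw <- readBin(con, "integer", 1, size = 4)
  H <- abs(Hraw)
  readBin(con, "integer", 1, size = 2)            # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (bpp != 24L || comp != 0L)
    stop("only 24-bit uncompressed BMP is supported")
  seek(con, offset)
  stride <- ((W * 3 + 3) %/% 4) * 4
  raw <- readBin(con, "raw", stride * H)
  px <- as.integer(raw)
  img <- array(0, dim = c(H, W, 3))
  for (r in seq_len(H)) {
    row <- px[((r - 1) * stride + 1):((r - 1) * stride + 3 * W)]
    i <- if (Hraw > 0) H - r + 1 else r   # bottom-up unless height < 0
    img[i, , 3] <- row[seq(1, 3 * W, 3)]
    img[i, , 2] <- row[seq(2, 3 * W, 3)]
    img[i, , 1] <- row[seq(3, 3 * W, 3)]
  }
  img / 255
}

#' Minimal 24-bit uncompressed BMP writer
#' @param img H x W x 3 array in \[0, 1\].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bmp <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  H <- dim(img)[1]; W <- dim(img)[2]
  stride <- ((W * 3 + 3) %/% 4) * 4
  data_size <- stride * H
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4d)), con)
  writeBin(as.integer(54 + data_size), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(54L, con, size = 4)                    # pixel data offset
  writeBin(40L, con, size = 4)                    # BITMAPINFOHEADER
  writeBin(as.integer(W), con, size = 4)
  writeBin(as.integer(H), con, size = 4)
  writeBin(1L, con, size = 2)
  writeBin(24L, con, size = 2)
  writeBin(0L, con, size = 4)                     # BI_RGB
  writeBin(as.integer(data_size), con, size = 4)
  writeBin(rep(2835L, 2), con, size = 4)          # 72 dpi
  writeBin(rep(0L, 2), con, size = 4)
  q <- function(x) as.integer(pmin(255, pmax(0, round(x * 255))))
  pad <- as.raw(rep(0, stride - 3 * W))
  for (r in seq_len(H)) {
    i <- H - r + 1                                 # bottom-up
    row <- as.raw(as.vector(rbind(q(img[i, , 3]), q(img[i, , 2]),
                                  q(img[i, , 1]))))
    writeBin(c(row, pad), con)
  }
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' On disk masks are 0 (background) / 255 (gland); in memory \{0, 1\}.
#' @param path PNG file.
#' @return an integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- (m > 0.5) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask as a 0/255 PNG
#' @param mask 0/1 matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- .as_binary_matrix(mask)
  png::writePNG(mask + 0.0, path)
  invisible(path)
}

#' In-memory polygon annotation document
#'
#' The structure mirrors a LabelMe JSON export: an image size and a list
#' of labelled polygons with vertex coordinates in pixels (x = column,
#' y = row, 0-based, origin at the top-left corner).
#'
#' @param width,height image size in px.
#' @param shapes list of shapes, each a list with \code{label} (string)
#'   and \code{points} (n x 2 numeric matrix of x, y vertices, n >= 3).
#' @return a list of class \code{"annotation_doc"}.
#' @export
annotation_doc <- function(width, height, shapes = list()) {
  for (k in seq_along(shapes)) {
    p <- shapes[[k]]$points
    if (is.null(dim(p)) || nrow(p) < 3)
      stop("polygon ", k, " is malformed: fewer than 3 vertices")
    if (any(p[, 1] < 0 | p[, 1] > width | p[, 2] < 0 | p[, 2] > height))
      stop("polygon ", k, " has vertices outside the image bounds")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 shapes = shapes),
            class = "annotation_doc")
}

#' Read a LabelMe-style JSON annotation file
#'
#' Reads the polygon fields of a LabelMe export (keys \code{imageWidth},
#' \code{imageHeight}, \code{shapes[\{label, points\}]}); embedded image
#' data is ignored.
#'
#' @param path JSON file.
#' @return an \code{"annotation_doc"}.
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight))
    stop("missing imageWidth/imageHeight in ", path)
  shapes <- lapply(doc$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    list(label = if (is.null(s$label)) "gland" else s$label, points = pts)
  })
  annotation_doc(doc$imageWidth, doc$imageHeight, shapes)
}

#' Write an annotation document as LabelMe-style JSON
#' @param doc an \code{"annotation_doc"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_labelme <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_doc"))
  out <- list(imageWidth = doc$width, imageHeight = doc$height,
              shapes = lapply(doc$shapes, function(s)
                list(label = s$label,
                     points = lapply(seq_len(nrow(s$points)), function(i)
                       as.numeric(s$points[i, ])))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize polygon annotations into a binary mask
#'
#' A pixel is foreground iff its center (x + 0.5, y + 0.5) lies inside
#' any polygon under the even-odd rule, implemented as a scanline fill
#' with half-open spans (a center exactly on a left span edge is inside,
#' on a right edge outside).
#'
#' @param doc an \code{"annotation_doc"}.
#' @param width,height output mask size; defaults to the document's.
#' @return an integer 0/1 matrix (height x width).
#' @export
rasterize_annotation <- function(doc, width = doc$width,
                                 height = doc$height) {
  stopifnot(inherits(doc, "annotation_doc"))
  mask <- matrix(0L, height, width)
  for (k in seq_along(doc$shapes)) {
    p <- doc$shapes[[k]]$points
    if (is.null(dim(p)) || nrow(p) < 3)
      stop("polygon ", k, " is malformed: fewer than 3 vertices")
    xs <- p[, 1]; ys <- p[, 2]
    nx <- length(xs)
    x2 <- xs[c(2:nx, 1)]; y2 <- ys[c(2:nx, 1)]
    poly <- matrix(0L, height, width)
    for (i0 in 0:(height - 1)) {
      yc <- i0 + 0.5
      cross <- ((ys <= yc & yc < y2) | (y2 <= yc & yc < ys))
      if (!any(cross)) next
      cx <- xs[cross] + (yc - ys[cross]) * (x2[cross] - xs[cross]) /
        (y2[cross] - ys[cross])
      cx <- sort(cx)
      for (s in seq(1, length(cx) - 1, by = 2)) {
        j0 <- ceiling(cx[s] - 0.5)
        j1 <- ceiling(cx[s + 1] - 0.5) - 1
        j0 <- max(j0, 0); j1 <- min(j1, width - 1)
        if (j0 <= j1) poly[i0 + 1, (j0 + 1):(j1 + 1)] <- 1L
      }
    }
    mask <- mask | poly
  }
  mask <- mask + 0L
  storage.mode(mask) <- "integer"
  mask
}

#' Random train/validation split
#'
#' Uniformly shuffles the items under the given seed and assigns the
#' first \code{floor(fraction * n)} to the training set; deterministic
#' per seed. Items may be tiles (random-by-tile split) or leaf/image
#' identifiers (grouped, leakage-aware split).
#'
#' @param items list or vector of dataset items.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return a list of class \code{"dataset_split"} with \code{train},
#'   \code{validation}, \code{fraction}, \code{seed}.
#' @export
split_dataset <- function(items, fraction = 0.8, seed = 1L) {
  n <- length(items)
  if (n < 2) stop("need at least 2 items to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  ntrain <- floor(fraction * n)
  structure(list(train = items[perm[seq_len(ntrain)]],
                 validation = items[perm[(ntrain + 1):n]],
                 fraction = fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Write a set of scenes to disk with a manifest
#'
#' Each scene's image is written as PNG (or BMP), its mask as a 0/255
#' PNG, and a manifest CSV summarises scene id, seed, count, density
#' level and file paths.
#'
#' @param scenes list of \code{"leaf_scene"} objects.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param format "png" or "bmp" for the images.
#' @return the manifest data frame, invisibly.
#' @export
write_scene_set <- function(scenes, dir, prefix = "scene", format = "png") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(k) {
    sc <- scenes[[k]]
    stopifnot(inherits(sc, "leaf_scene"))
    ip <- file.path(dir, sprintf("%s_%04d.%s", prefix, k, format))
    mp <- file.path(dir, sprintf("%s_%04d_mask.png", prefix, k))
    write_image(sc$image, ip)
    write_mask(sc$mask, mp)
    data.frame(scene_id = sprintf("%s_%04d", prefix, k),
               seed = sc$config$seed, count = sc$count,
               density_level = sc$density_level,
               image_path = ip, mask_path = mp)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- data.frame(scene_id = character(0), seed = integer(0),
                           count = integer(0), density_level = integer(0),
                           image_path = character(0),
                           mask_path = character(0))
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
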