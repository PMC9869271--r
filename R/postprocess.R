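#' Shape-feature filter configuration
#'
#' Controls the post-filtering applied to a binarised segmentation before
#' counting. The published pipeline keeps connected domains with area
#' between 2 and 938744 px (the lower bound removes sub-gland specks;
#' the upper bound is far larger than any gland and is effectively
#' unbounded, retained verbatim) and optionally applies a morphological
#' closing first.
#'
#' @param min_area,max_area inclusive area bounds in px.
#' @param closing_radius disk radius for the closing; 0 disables it. Note
#'   that closing can merge adjacent glands into one domain (an
#'   undercounting failure mode), so counting workflows often disable it.
#' @param connectivity 4 or 8 (default 8: diagonally touching gland pixels
#'   belong to one gland).
#' @return a list of class \code{"filter_config"}.
#' @export
filter_config <- function(min_area = 2L, max_area = 938744L,
                          closing_radius = 1L, connectivity = 8L) {
  if (min_area < 1 || max_area < min_area)
    stop("need 0 < min_area <= max_area")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (closing_radius < 0) stop("closing_radius must be >= 0")
  structure(list(min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 closing_radius = as.integer(closing_radius),
                 connectivity = as.integer(connectivity)),
            class = "filter_config")
}

#' Label connected domains of a binary mask
#'
#' Two foreground pixels share a label iff they are connected under the
#' chosen adjacency (equivalent to a flood fill). Region ids are dense
#' 1..K in scan order.
#'
#' @param mask binary (0/1) matrix.
#' @param connectivity 4 or 8.
#' @return an object of class \code{"region_set"}: \code{labels} (integer
#'   matrix, 0 = background), \code{regions} (data frame with
#'   \code{region_id}, \code{area}, \code{centroid_x}, \code{centroid_y},
#'   \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax}; x = column,
#'   y = row, 0-based) and \code{connectivity}.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- .as_binary_matrix(mask)
  labels <- label_components_cpp(mask, as.integer(connectivity))
  k <- attr(labels, "n_regions")
  if (k == 0L) {
    regions <- data.frame(region_id = integer(0), area = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          xmin = integer(0), xmax = integer(0),
                          ymin = integer(0), ymax = integer(0))
  } else {
    fg <- which(labels > 0L, arr.ind = TRUE)
    id <- labels[labels > 0L]
    row0 <- fg[, 1] - 1L
    col0 <- fg[, 2] - 1L
    regions <- data.frame(
      region_id = seq_len(k),
      area = as.integer(tabulate(id, nbins = k)),
      centroid_x = as.numeric(tapply(col0, id, mean)),
      centroid_y = as.numeric(tapply(row0, id, mean)),
      xmin = as.integer(tapply(col0, id, min)),
      xmax = as.integer(tapply(col0, id, max)),
      ymin = as.integer(tapply(row0, id, min)),
      ymax = as.integer(tapply(row0, id, max)))
  }
  structure(list(labels = labels, regions = regions,
                 connectivity = as.integer(connectivity)),
            class = "region_set")
}

#' Morphological closing with a disk structuring element
#'
#' Dilation followed by erosion; fills gaps smaller than the disk and is
#' extensive (output contains the input). Radius 0 is the identity.
#'
#' @param mask binary (0/1) matrix.
#' @param radius disk radius in px.
#' @return a binary integer matrix.
#' @export
morphological_close <- function(mask, radius = 1L) {
  mask <- .as_binary_matrix(mask)
  if (radius == 0) return(mask)
  r <- as.integer(radius)
  # embed in a zero frame of width r so the result equals the closing on
  # the infinite zero-padded domain (keeps closing extensive at borders)
  H <- nrow(mask); W <- ncol(mask)
  big <- matrix(0L, H + 2L * r, W + 2L * r)
  big[(r + 1L):(r + H), (r + 1L):(r + W)] <- mask
  closed <- binary_morph_cpp(binary_morph_cpp(big, r, TRUE), r, FALSE)
  closed[(r + 1L):(r + H), (r + 1L):(r + W), drop = FALSE]
}

#' Keep regions whose area lies within the configured bounds
#'
#' Regions with \code{min_area <= area <= max_area} survive; all others
#' are erased to background and the surviving ids re-densified to 1..K'.
#'
#' @param regions a \code{"region_set"} from [label_components()].
#' @param config a [filter_config()].
#' @return a filtered \code{"region_set"}.
#' @export
filter_regions <- function(regions, config = filter_config()) {
  stopifnot(inherits(regions, "region_set"),
            inherits(config, "filter_config"))
  keep <- regions$regions$area >= config$min_area &
    regions$regions$area <= config$max_area
  old_ids <- regions$regions$region_id[keep]
  remap <- integer(max(regions$regions$region_id, 0L))
  remap[old_ids] <- seq_along(old_ids)
  labels <- regions$labels
  labels[labels > 0L] <- ifelse(labels[labels > 0L] %in% old_ids,
                                remap[labels[labels > 0L]], 0L)
  tab <- regions$regions[keep, , drop = FALSE]
  tab$region_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(labels, "n_regions") <- nrow(tab)
  structure(list(labels = labels, regions = tab,
                 connectivity = regions$connectivity),
            class = "region_set")
}

#' Count glands in a binary segmentation mask
#'
#' The full counting chain: optional morphological closing, connected
#' domain labeling, area filtering, and the number of surviving domains.
#'
#' @param mask binary (0/1) matrix.
#' @param config a [filter_config()].
#' @return integer count.
#' @export
count_glands <- function(mask, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  m <- morphological_close(mask, config$closing_radius)
  rs <- filter_regions(label_components(m, config$connectivity), config)
  nrow(rs$regions)
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", nrow(x$regions), "regions (",
      x$connectivity, "-connectivity)\n", sep = "")
  if (nrow(x$regions) > 0)
    print(utils::head(x$regions, 10))
  invisible(x)
}

#' Write a region table to CSV
#' @param regions a \code{"region_set"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_region_table <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  utils::write.csv(regions$regions, path, row.names = FALSE)
  invisible(path)
}

.as_binary_matrix <- function(mask) {
  if (!is.matrix(mask)) {
    if (is.array(mask) && length(dim(mask)) == 2L) mask <- as.matrix(mask)
    else stop("mask must be a matrix")
  }
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop("mask must be binary (0/1)")
  storage.mode(mask) <- "integer"
  mask
}
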