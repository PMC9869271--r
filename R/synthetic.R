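#' Configuration for a synthetic leaf scene
#'
#' Describes a generated leaf-like RGB image with dark, near-circular
#' pigment-gland spots on a green background, plus dark curvilinear
#' vein-like confounders. At the working scale of ~45 um/px a 100x100 px
#' tile corresponds to the 4.5 x 4.5 mm area over which gland densities
#' are defined, and the typical 100-400 um gland diameter maps to roughly
#' 2-9 px, i.e. spot radii of about 1-5 px.
#'
#' @param width,height scene size in px.
#' @param spot_count number of glands to place (>= 0).
#' @param spot_radius_range min/max spot radius in px (min >= 1).
#' @param spot_intensity gray-level range (0-1 scale) of the dark spots.
#' @param background_green gray-level range of the green channel of the
#'   leaf background.
#' @param vein_count number of vein-like curves drawn on the image (never
#'   on the mask).
#' @param vein_width vein stroke width in px.
#' @param vein_darkness gray level of vein pixels (between spot and
#'   background levels, so veins are plausible confounders).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed; the same config generates bit-identical
#'   scenes.
#' @param allow_overlap if TRUE, spots may overlap (the ground-truth count
#'   then no longer matches the component count; used for stress tests
#'   only).
#' @param um_per_px physical scale; only used to document provenance, the
#'   generator works in pixels.
#' @return a list of class \code{"scene_config"}.
#' @export
scene_config <- function(width = 100L, height = 100L, spot_count = 30L,
                         spot_radius_range = c(1, 5),
                         spot_intensity = c(0.05, 0.25),
                         background_green = c(0.35, 0.55),
                         vein_count = 2L, vein_width = 2L,
                         vein_darkness = 0.30, noise_sd = 0.02,
                         seed = 1L, allow_overlap = FALSE,
                         um_per_px = 45) {
  if (spot_count < 0) stop("spot_count must be >= 0")
  if (spot_radius_range[1] < 1) stop("minimum spot radius is 1 px")
  if (width < 1 || height < 1) stop("scene must be at least 1x1 px")
  structure(list(width = as.integer(width), height = as.integer(height),
                 spot_count = as.integer(spot_count),
                 spot_radius_range = spot_radius_range,
                 spot_intensity = spot_intensity,
                 background_green = background_green,
                 vein_count = as.integer(vein_count),
                 vein_width = vein_width, vein_darkness = vein_darkness,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap),
                 um_per_px = um_per_px),
            class = "scene_config")
}

#' Density level of a gland count
#'
#' Strata used to bin tiles by gland density per 4.5 x 4.5 mm (100x100 px)
#' area: counts below 40 are level 1, counts from 40 up to (but not
#' including) 80 are level 2, counts of 80 or more are level 3. The
#' boundary counts 40 and 80 fall in the upper level (half-open bins), so
#' the three bins partition all non-negative counts.
#'
#' @param count non-negative integer vector.
#' @return integer vector of levels in \{1, 2, 3\}.
#' @export
assign_density_level <- function(count) {
  if (any(count < 0)) stop("count must be >= 0")
  ifelse(count < 40, 1L, ifelse(count < 80, 2L, 3L))
}

# linear pixel indices (into an H x W plane) of the disk around (cy, cx)
.disk_indices <- function(cy, cx, r, H, W) {
  i0 <- max(1L, floor(cy - r)); i1 <- min(H, ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(W, ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  sel <- outer((ii - cy)^2, (jj - cx)^2, `+`) <= r^2
  idx <- outer(ii, (jj - 1L) * H, `+`)
  idx[sel]
}

#' Generate a synthetic leaf scene
#'
#' Places \code{spot_count} non-overlapping dark disks (rejection
#' sampling with a 2 px clearance, which guarantees that the ground-truth
#' count equals the number of 8-connected mask components), draws
#' vein-like dark curves on the image only, and adds pixel noise.
#' Deterministic for a given config (including its seed).
#'
#' @param config a [scene_config()].
#' @return an object of class \code{"leaf_scene"}: \code{image} (H x W x 3
#'   array in \[0, 1\]), \code{mask} (H x W integer 0/1 matrix),
#'   \code{count}, \code{density_level} (count scaled to the 100x100 px
#'   reference area), and \code{config}.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  H <- config$height; W <- config$width
  rr <- config$spot_radius_range

  # background: per-scene green level with mild spatial variation
  g0 <- stats::runif(1, config$background_green[1], config$background_green[2])
  trend <- outer(seq(-0.02, 0.02, length.out = H),
                 seq(-0.02, 0.02, length.out = W), `+`)
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- (g0 + trend) * 0.62
  img[, , 2] <- g0 + trend
  img[, , 3] <- (g0 + trend) * 0.45

  # spots: rejection-sampled non-overlapping disks
  n <- config$spot_count
  cy <- cx <- rad <- numeric(0)
  if (n > 0) {
    max_attempts <- 500L * n + 200L
    attempts <- 0L
    while (length(rad) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- stats::runif(1, rr[1], rr[2])
      if (2 * r + 2 > min(H, W)) next
      y <- stats::runif(1, r + 1, H - r)
      x <- stats::runif(1, r + 1, W - r)
      ok <- config$allow_overlap ||
        length(rad) == 0 ||
        all(sqrt((cy - y)^2 + (cx - x)^2) >= rad + r + 2)
      if (ok) {
        cy <- c(cy, y); cx <- c(cx, x); rad <- c(rad, r)
      }
    }
    if (length(rad) < n)
      stop("could not place ", n, " non-overlapping spots in ", W, "x", H,
           " px; achieved maximum was ", length(rad),
           " (density too high for the area/radius range)")
  }

  # veins: random-walk curves stamped on the image, never on the mask
  npix <- H * W
  vein_scale <- c(0.85, 1, 0.7)
  vr <- config$vein_width / 2
  vein_idx <- vector("list", config$vein_count)
  for (v in seq_len(config$vein_count)) {
    if (stats::runif(1) < 0.5) {
      pos <- c(stats::runif(1, 1, H), 1)
      ang0 <- stats::runif(1, -pi / 4, pi / 4)
    } else {
      pos <- c(1, stats::runif(1, 1, W))
      ang0 <- pi / 2 + stats::runif(1, -pi / 4, pi / 4)
    }
    steps <- ceiling(1.6 * max(H, W))
    angs <- ang0 + cumsum(stats::rnorm(steps, 0, 0.08))
    py <- pos[1] + c(0, cumsum(sin(angs)))
    px <- pos[2] + c(0, cumsum(cos(angs)))
    inside <- py >= 1 & py <= H & px >= 1 & px <= W
    stopidx <- if (all(inside)) length(py) else which(!inside)[1] - 1L
    if (stopidx < 1) next
    pts <- unique(cbind(round(py[1:stopidx]), round(px[1:stopidx])))
    vein_idx[[v]] <- unlist(lapply(seq_len(nrow(pts)), function(s)
      .disk_indices(pts[s, 1], pts[s, 2], vr, H, W)))
  }
  vein_idx <- unique(unlist(vein_idx))
  if (length(vein_idx)) {
    for (c in 1:3)
      img[vein_idx + (c - 1L) * npix] <- config$vein_darkness * vein_scale[c]
  }

  mask <- matrix(0L, H, W)
  spot_scale <- c(1.1, 1, 0.8)
  for (k in seq_along(rad)) {
    dark <- stats::runif(1, config$spot_intensity[1],
                         config$spot_intensity[2])
    idx <- .disk_indices(cy[k], cx[k], rad[k], H, W)
    for (c in 1:3) img[idx + (c - 1L) * npix] <- dark * spot_scale[c]
    mask[idx] <- 1L
  }

  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd),
                       dim = dim(img))
  img[img < 0] <- 0
  img[img > 1] <- 1

  per_ref_area <- config$spot_count * 1e4 / (W * H)
  structure(list(image = img, mask = mask, count = config$spot_count,
                 density_level = assign_density_level(round(per_ref_area)),
                 config = config),
            class = "leaf_scene")
}

#' @export
print.leaf_scene <- function(x, ...) {
  cat(sprintf("Leaf scene %dx%d px: %d glands (density level %d), seed %d\n",
              x$config$width, x$config$height, x$count, x$density_level,
              x$config$seed))
  invisible(x)
}

# flip helpers shared by image (3-D) and mask (2-D)
.flip_raster <- function(r, horizontal, vertical) {
  d <- dim(r)
  ri <- if (vertical) rev(seq_len(d[1])) else seq_len(d[1])
  ci <- if (horizontal) rev(seq_len(d[2])) else seq_len(d[2])
  if (length(d) == 2L) r[ri, ci, drop = FALSE] else r[ri, ci, , drop = FALSE]
}

#' Four-fold flip augmentation
#'
#' Expands each scene into four variants: the original, its horizontal
#' flip, its vertical flip, and its 180-degree rotation (both flips
#' composed). Masks are transformed identically to images, so mask area
#' and component count are preserved; 9 scenes become 36.
#'
#' @param scenes a \code{"leaf_scene"} or a non-empty list of them.
#' @return a list of 4x as many scenes.
#' @export
augment_flips <- function(scenes) {
  if (inherits(scenes, "leaf_scene")) scenes <- list(scenes)
  if (length(scenes) == 0) stop("scene list must be non-empty")
  variants <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                   c(TRUE, TRUE))
  out <- vector("list", 4L * length(scenes))
  k <- 0L
  for (sc in scenes) {
    stopifnot(inherits(sc, "leaf_scene"))
    for (v in variants) {
      k <- k + 1L
      out[[k]] <- structure(
        list(image = .flip_raster(sc$image, v[1], v[2]),
             mask = .flip_raster(sc$mask, v[1], v[2]),
             count = sc$count, density_level = sc$density_level,
             config = sc$config),
        class = "leaf_scene")
    }
  }
  out
}

#' Generate a set of training/evaluation tiles at a density level
#'
#' Convenience generator for network-sized tiles: each tile is a
#' standalone scene of \code{size} px whose gland count is drawn from the
#' requested density stratum (defined per 100x100 px reference area and
#' scaled to the tile area). Denser strata use smaller spot radii, which
#' both matches how crowded glands look on real leaves and keeps
#' non-overlapping placement feasible.
#'
#' @param n number of tiles.
#' @param density_level 1, 2 or 3.
#' @param size tile side in px (default 120, the network input).
#' @param seed base seed; tile k uses \code{seed + k}.
#' @param ... further arguments passed to [scene_config()] (e.g.
#'   \code{vein_count}).
#' @return a list with \code{x} (list of H x W x 3 arrays), \code{y} (list
#'   of 0/1 matrices), \code{counts} (integer vector) and \code{scenes}.
#' @export
generate_tile_set <- function(n, density_level = 1L, size = 120L,
                              seed = 1L, ...) {
  stopifnot(density_level %in% 1:3, n >= 0)
  area_factor <- (size * size) / 1e4
  range_ref <- switch(density_level, `1` = c(5, 39), `2` = c(40, 79),
                      `3` = c(80, 130))
  radii <- switch(density_level, `1` = c(1, 5), `2` = c(1, 4),
                  `3` = c(1, 3))
  scenes <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(seed + k)
    cnt <- round(sample(range_ref[1]:range_ref[2], 1) * area_factor)
    scenes[[k]] <- generate_scene(scene_config(
      width = size, height = size, spot_count = cnt,
      spot_radius_range = radii, seed = seed + k, ...))
  }
  list(x = lapply(scenes, `[[`, "image"),
       y = lapply(scenes, `[[`, "mask"),
       counts = vapply(scenes, `[[`, integer(1), "count"),
       scenes = scenes)
}
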