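# shared fixture builders and brute-force oracles

random_mask <- function(h, w, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w)
}

# brute-force flood-fill labeling oracle (BFS over a queue)
floodfill_labels <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (t in seq_len(nrow(nb))) {
          qi <- p[1] + nb[t, 1]; qj <- p[2] + nb[t, 2]
          if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
              mask[qi, qj] == 1 && lab[qi, qj] == 0L) {
            lab[qi, qj] <- k
            queue <- c(queue, list(c(qi, qj)))
          }
        }
      }
    }
  }
  lab
}

# brute-force even-odd point-in-polygon test at pixel centers
pip_rasterize <- function(points, width, height) {
  mask <- matrix(0L, height, width)
  n <- nrow(points)
  for (i0 in 0:(height - 1)) for (j0 in 0:(width - 1)) {
    px <- j0 + 0.5; py <- i0 + 0.5
    crossings <- 0L
    for (e in seq_len(n)) {
      x1 <- points[e, 1]; y1 <- points[e, 2]
      x2 <- points[e %% n + 1, 1]; y2 <- points[e %% n + 1, 2]
      if ((y1 <= py && py < y2) || (y2 <= py && py < y1)) {
        xc <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (px >= xc) NULL else crossings <- crossings + 1L
      }
    }
    if (crossings %% 2L == 1L) mask[i0 + 1, j0 + 1] <- 1L
  }
  mask
}

# a tiny model whose checkpoint is quick to build in CLI tests
tiny_model <- function(size = 24, seed = 1) {
  build_network(network_spec(input_size = size, base_channels = 2),
                seed = seed)
}
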