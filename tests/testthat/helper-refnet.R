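# Independent double-precision reference implementation of the network's
# forward and backward passes, written directly from the layer definitions
# (im2col-free, plain loops / base matrix ops). Used as an oracle for the
# package's single-precision compiled implementation.

ref_im2col <- function(x, H, W) {
  C <- ncol(x)
  cols <- matrix(0, H * W, 9 * C)
  k <- 0
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1
    for (c in 1:C) for (j in 1:W) for (i in 1:H) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        cols[i + (j - 1) * H, (k - 1) * C + c] <- x[ii + (jj - 1) * H, c]
    }
  }
  cols
}

ref_col2im <- function(cols, H, W, C) {
  x <- matrix(0, H * W, C)
  k <- 0
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1
    for (c in 1:C) for (j in 1:W) for (i in 1:H) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        x[ii + (jj - 1) * H, c] <- x[ii + (jj - 1) * H, c] +
          cols[i + (j - 1) * H, (k - 1) * C + c]
    }
  }
  x
}

ref_maxpool <- function(x, H, W) {
  C <- ncol(x); Ho <- H / 2; Wo <- W / 2
  y <- matrix(0, Ho * Wo, C); am <- matrix(0L, Ho * Wo, C)
  for (c in 1:C) for (jo in 1:Wo) for (io in 1:Ho) {
    idx <- c(2*io-1 + (2*jo-2)*H, 2*io + (2*jo-2)*H,
             2*io-1 + (2*jo-1)*H, 2*io + (2*jo-1)*H)
    v <- x[idx, c]
    b <- which.max(v)  # first max, as in the compiled version (> comparison)
    y[io + (jo-1)*Ho, c] <- v[b]
    am[io + (jo-1)*Ho, c] <- idx[b]
  }
  list(y = y, am = am)
}

ref_maxpool_back <- function(dy, am, H, W) {
  C <- ncol(dy)
  dx <- matrix(0, H * W, C)
  for (c in 1:C) for (p in seq_len(nrow(dy)))
    dx[am[p, c], c] <- dx[am[p, c], c] + dy[p, c]
  dx
}

ref_upsample <- function(x, H, W) {
  C <- ncol(x); Ho <- 2 * H
  y <- matrix(0, 4 * H * W, C)
  for (c in 1:C) for (j in 1:W) for (i in 1:H) {
    v <- x[i + (j-1)*H, c]
    for (a in 0:1) for (b in 0:1)
      y[2*i-1+a + (2*j-2+b)*Ho, c] <- v
  }
  y
}

ref_upsample_back <- function(dy, H, W) {
  C <- ncol(dy); Ho <- 2 * H
  dx <- matrix(0, H * W, C)
  for (c in 1:C) for (j in 1:W) for (i in 1:H) {
    s <- 0
    for (a in 0:1) for (b in 0:1)
      s <- s + dy[2*i-1+a + (2*j-2+b)*Ho, c]
    dx[i + (j-1)*H, c] <- s
  }
  dx
}

# forward in training mode over a batch (list of (H*W) x C matrices);
# returns activations needed for backward
ref_convbn_forward <- function(xs, H, W, Wt, g, be, eps = 1e-5) {
  B <- length(xs)
  z <- lapply(xs, function(x) ref_im2col(x, H, W) %*% Wt)
  Cout <- ncol(Wt)
  N <- B * H * W
  mu <- colSums(do.call(rbind, z)) / N
  va <- colSums(do.call(rbind, lapply(z, function(m) sweep(m, 2, mu)^2))) / N
  invstd <- 1 / sqrt(va + eps)
  xhat <- lapply(z, function(m) sweep(sweep(m, 2, mu), 2, invstd, `*`))
  a <- lapply(xhat, function(m) pmax(sweep(sweep(m, 2, g, `*`), 2, be, `+`), 0))
  list(a = a, xhat = xhat, invstd = invstd, mu = mu, va = va, xin = xs,
       H = H, W = W, Wt = Wt, g = g)
}

ref_convbn_backward <- function(fw, dA) {
  B <- length(dA); H <- fw$H; W <- fw$W
  Cout <- ncol(fw$Wt); Cin <- nrow(fw$Wt) / 9
  N <- B * H * W
  dBn <- lapply(seq_len(B), function(b) dA[[b]] * (fw$a[[b]] > 0))
  dg <- Reduce(`+`, lapply(seq_len(B), function(b)
    colSums(dBn[[b]] * fw$xhat[[b]])))
  dbe <- Reduce(`+`, lapply(dBn, colSums))
  dxhat <- lapply(dBn, function(m) sweep(m, 2, fw$g, `*`))
  s1 <- Reduce(`+`, lapply(dxhat, colSums))
  s2 <- Reduce(`+`, lapply(seq_len(B), function(b)
    colSums(dxhat[[b]] * fw$xhat[[b]])))
  dW <- matrix(0, nrow(fw$Wt), Cout)
  dX <- vector("list", B)
  for (b in seq_len(B)) {
    dz <- sweep(dxhat[[b]], 2, s1 / N) -
      sweep(fw$xhat[[b]], 2, s2 / N, `*`)
    dz <- sweep(dz, 2, fw$invstd, `*`)
    cols <- ref_im2col(fw$xin[[b]], H, W)
    dW <- dW + t(cols) %*% dz
    dX[[b]] <- ref_col2im(dz %*% t(fw$Wt), H, W, Cin)
  }
  list(dW = dW, dg = dg, dbe = dbe, dX = dX)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full forward + MSE loss + backward in double precision
ref_net_grad <- function(params, xs_arr, ys, eps = 1e-5) {
  B <- length(xs_arr)
  H <- dim(xs_arr[[1]])[1]; W <- dim(xs_arr[[1]])[2]
  xs <- lapply(xs_arr, function(a) matrix(a, H * W, dim(a)[3]))
  f1 <- ref_convbn_forward(xs, H, W, params$W1, params$g1, params$be1, eps)
  f2 <- ref_convbn_forward(f1$a, H, W, params$W2, params$g2, params$be2, eps)
  u1 <- lapply(f2$a, ref_upsample, H = H, W = W)
  f3 <- ref_convbn_forward(u1, 2*H, 2*W, params$W3, params$g3, params$be3, eps)
  f4 <- ref_convbn_forward(f3$a, 2*H, 2*W, params$W4, params$g4, params$be4, eps)
  u2 <- lapply(f4$a, ref_upsample, H = 2*H, W = 2*W)
  f5 <- ref_convbn_forward(u2, 4*H, 4*W, params$W5, params$g5, params$be5, eps)
  f6 <- ref_convbn_forward(f5$a, 4*H, 4*W, params$W6, params$g6, params$be6, eps)
  p1 <- lapply(f6$a, ref_maxpool, H = 4*H, W = 4*W)
  c1 <- lapply(seq_len(B), function(b) cbind(p1[[b]]$y, f4$a[[b]]))
  f7 <- ref_convbn_forward(c1, 2*H, 2*W, params$W7, params$g7, params$be7, eps)
  f8 <- ref_convbn_forward(f7$a, 2*H, 2*W, params$W8, params$g8, params$be8, eps)
  p2 <- lapply(f8$a, ref_maxpool, H = 2*H, W = 2*W)
  c2 <- lapply(seq_len(B), function(b) cbind(p2[[b]]$y, f2$a[[b]]))
  f9 <- ref_convbn_forward(c2, H, W, params$W9, params$g9, params$be9, eps)
  f10 <- ref_convbn_forward(f9$a, H, W, params$W10, params$g10, params$be10, eps)
  out <- lapply(f10$a, function(a) pmax(a %*% cbind(params$Wh) + params$bh, 0))
  N <- B * H * W
  loss <- sum(vapply(seq_len(B), function(b)
    sum((out[[b]] - as.vector(ys[[b]]))^2), numeric(1))) / N

  dWh <- rep(0, length(params$Wh)); dbh <- 0
  d10 <- vector("list", B)
  for (b in seq_len(B)) {
    dout <- 2 / N * (out[[b]] - as.vector(ys[[b]])) * (out[[b]] > 0)
    dWh <- dWh + as.vector(t(f10$a[[b]]) %*% dout)
    dbh <- dbh + sum(dout)
    d10[[b]] <- dout %*% rbind(params$Wh)
  }
  b10 <- ref_convbn_backward(f10, d10)
  b9 <- ref_convbn_backward(f9, b10$dX)
  C8 <- ncol(params$W8)
  d8 <- lapply(seq_len(B), function(b)
    ref_maxpool_back(b9$dX[[b]][, 1:C8, drop = FALSE], p2[[b]]$am, 2*H, 2*W))
  dskip1 <- lapply(b9$dX, function(m) m[, -(1:C8), drop = FALSE])
  b8 <- ref_convbn_backward(f8, d8)
  b7 <- ref_convbn_backward(f7, b8$dX)
  C6 <- ncol(params$W6)
  d6 <- lapply(seq_len(B), function(b)
    ref_maxpool_back(b7$dX[[b]][, 1:C6, drop = FALSE], p1[[b]]$am, 4*H, 4*W))
  dskip2 <- lapply(b7$dX, function(m) m[, -(1:C6), drop = FALSE])
  b6 <- ref_convbn_backward(f6, d6)
  b5 <- ref_convbn_backward(f5, b6$dX)
  d4 <- lapply(seq_len(B), function(b)
    ref_upsample_back(b5$dX[[b]], 2*H, 2*W) + dskip2[[b]])
  b4 <- ref_convbn_backward(f4, d4)
  b3 <- ref_convbn_backward(f3, b4$dX)
  d2 <- lapply(seq_len(B), function(b)
    ref_upsample_back(b3$dX[[b]], H, W) + dskip1[[b]])
  b2 <- ref_convbn_backward(f2, d2)
  b1 <- ref_convbn_backward(f1, b2$dX)

  grads <- list()
  bl <- list(b1, b2, b3, b4, b5, b6, b7, b8, b9, b10)
  for (l in 1:10) {
    grads[[paste0("W", l)]] <- bl[[l]]$dW
    grads[[paste0("g", l)]] <- bl[[l]]$dg
    grads[[paste0("be", l)]] <- bl[[l]]$dbe
  }
  grads$Wh <- dWh
  grads$bh <- dbh
  list(loss = loss, grads = grads, out = out)
}

# evaluation-mode forward (running statistics) in double precision
ref_net_forward_eval <- function(params, running, x_arr, eps = 1e-5) {
  H <- dim(x_arr)[1]; W <- dim(x_arr)[2]
  cb <- function(x, h, w, l) {
    z <- ref_im2col(x, h, w) %*% params[[paste0("W", l)]]
    z <- sweep(z, 2, running[[paste0("rm", l)]])
    z <- sweep(z, 2, 1 / sqrt(running[[paste0("rv", l)]] + eps), `*`)
    z <- sweep(z, 2, params[[paste0("g", l)]], `*`)
    pmax(sweep(z, 2, params[[paste0("be", l)]], `+`), 0)
  }
  a1 <- cb(matrix(x_arr, H * W, dim(x_arr)[3]), H, W, 1)
  a2 <- cb(a1, H, W, 2)
  a3 <- cb(ref_upsample(a2, H, W), 2 * H, 2 * W, 3)
  a4 <- cb(a3, 2 * H, 2 * W, 4)
  a5 <- cb(ref_upsample(a4, 2 * H, 2 * W), 4 * H, 4 * W, 5)
  a6 <- cb(a5, 4 * H, 4 * W, 6)
  a7 <- cb(cbind(ref_maxpool(a6, 4 * H, 4 * W)$y, a4), 2 * H, 2 * W, 7)
  a8 <- cb(a7, 2 * H, 2 * W, 8)
  a9 <- cb(cbind(ref_maxpool(a8, 2 * H, 2 * W)$y, a2), H, W, 9)
  a10 <- cb(a9, H, W, 10)
  out <- pmax(a10 %*% cbind(params$Wh) + params$bh, 0)
  matrix(out, H, W)
}
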