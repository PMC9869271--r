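// Interpolation-first / pooling-second encoder-decoder ("Ipp" style) network:
// forward, backward and batch-norm statistics, hand-derived, single precision.
// Activations are stored as (H*W) x C matrices (column-major pixel index
// p = i + j*H), so a 3x3 "same" convolution is one im2col + one sgemm.
// im2col buffers are reused across layers and steps to keep the training
// loop memory-bandwidth-, not allocator-, bound.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::umat;

static fmat as_f(SEXP s) {
  arma::mat m = as<arma::mat>(s);
  return arma::conv_to<fmat>::from(m);
}
static fvec as_fv(SEXP s) {
  arma::vec v = as<arma::vec>(s);
  return arma::conv_to<fvec>::from(v);
}
static NumericMatrix to_R(const fmat& m) {
  arma::mat d = arma::conv_to<arma::mat>::from(m);
  return wrap(d);
}
static NumericVector to_Rv(const fvec& v) {
  arma::vec d = arma::conv_to<arma::vec>::from(v);
  return wrap(d);
}

// growable scratch buffer wrapped as an arma matrix without ownership
struct Workspace {
  std::vector<float> buf;
  fmat mat(arma::uword r, arma::uword c) {
    if (buf.size() < (size_t)r * c) buf.resize((size_t)r * c);
    return fmat(buf.data(), r, c, false, true);
  }
};

// im2col for a 3x3 same-padded (zeros) convolution, written into ws.
// x: (H*W) x C, result: (H*W) x (9*C); column block k*C + c holds x shifted
// by offset k (k enumerates (di,dj) in column-major order over {-1,0,1}^2).
// Only out-of-image slots are zeroed, the rest is overwritten.
static void im2col3(const fmat& x, int H, int W, fmat& cols) {
  const int C = x.n_cols;
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di, ++k) {
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      const int len = i1 - i0;
      for (int c = 0; c < C; ++c) {
        const float* src = x.colptr(c);
        float* dst = cols.colptr((size_t)k * C + c);
        if (dj == -1) std::memset(dst, 0, sizeof(float) * H);
        if (dj == 1) std::memset(dst + (size_t)(W - 1) * H, 0,
                                 sizeof(float) * H);
        for (int j = j0; j < j1; ++j) {
          if (di == -1) dst[j * H] = 0.0f;
          if (di == 1) dst[H - 1 + j * H] = 0.0f;
          if (len > 0)
            std::memcpy(dst + i0 + (size_t)j * H,
                        src + (i0 + di) + (size_t)(j + dj) * H,
                        sizeof(float) * len);
        }
      }
    }
  }
}

// 2x2 max pooling, stride 2; argmax pixel index recorded for the backward pass
static fmat maxpool2(const fmat& x, int H, int W, umat& argmax) {
  const int C = x.n_cols, Ho = H / 2, Wo = W / 2;
  fmat y((arma::uword)Ho * Wo, C);
  argmax.set_size((arma::uword)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int base = 2 * io + 2 * jo * H;
        int best = base;
        float v = src[base];
        const int cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (src[cand[t]] > v) { v = src[cand[t]]; best = cand[t]; }
        y(io + (size_t)jo * Ho, c) = v;
        argmax(io + (size_t)jo * Ho, c) = best;
      }
    }
  }
  return y;
}

static fmat maxpool2_back(const fmat& dy, const umat& argmax, int H, int W) {
  const int C = dy.n_cols;
  fmat dx((arma::uword)H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* d = dx.colptr(c);
    for (arma::uword p = 0; p < dy.n_rows; ++p) d[argmax(p, c)] += dy(p, c);
  }
  return dx;
}

// nearest-neighbour x2 upsampling: out(2i+a, 2j+b) = in(i, j)
static fmat upsample2(const fmat& x, int H, int W) {
  const int C = x.n_cols, Ho = 2 * H, Wo = 2 * W;
  fmat y((arma::uword)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* dst = y.colptr(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const float v = src[i + (size_t)j * H];
        const size_t i2 = 2 * i, j2 = 2 * j;
        dst[i2 + j2 * Ho] = v;
        dst[i2 + 1 + j2 * Ho] = v;
        dst[i2 + (j2 + 1) * Ho] = v;
        dst[i2 + 1 + (j2 + 1) * Ho] = v;
      }
    }
  }
  return y;
}

static fmat upsample2_back(const fmat& dy, int H, int W) {
  const int C = dy.n_cols, Ho = 2 * H;
  fmat dx((arma::uword)H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* src = dy.colptr(c);
    float* dst = dx.colptr(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const size_t i2 = 2 * i, j2 = 2 * j;
        dst[i + (size_t)j * H] = src[i2 + j2 * Ho] + src[i2 + 1 + j2 * Ho] +
                                 src[i2 + (j2 + 1) * Ho] +
                                 src[i2 + 1 + (j2 + 1) * Ho];
      }
    }
  }
  return dx;
}

static inline void relu_inplace(fmat& m) {
  float* p = m.memptr();
  const size_t n = m.n_elem;
  for (size_t q = 0; q < n; ++q) p[q] = p[q] > 0.0f ? p[q] : 0.0f;
}

// conv3x3 (no bias) + batch norm + ReLU, with cached state for backward.
// Inputs are not cached here; the caller keeps every activation alive and
// passes the layer input again to backward().
struct ConvBN {
  fmat Wt;          // (9*Cin) x Cout
  fvec g, be;       // batch-norm scale/shift, length Cout
  int H = 0, W = 0;
  std::vector<fmat> xhat, aout, cols_cache;
  fvec mean, var, invstd;
  fmat dW;
  fvec dg, dbe;

  const std::vector<fmat>& forward_train(const std::vector<fmat>& in,
                                         int H_, int W_, double eps,
                                         Workspace& ws) {
    H = H_; W = W_;
    const int B = in.size(), Cout = Wt.n_cols;
    std::vector<fmat> z(B);
    cols_cache.resize(B);
    for (int b = 0; b < B; ++b) {
      if (cols_cache[b].n_rows != (arma::uword)H * W ||
          cols_cache[b].n_cols != Wt.n_rows)
        cols_cache[b].set_size((arma::uword)H * W, Wt.n_rows);
      im2col3(in[b], H, W, cols_cache[b]);
      z[b] = cols_cache[b] * Wt;
    }
    const double N = (double)B * H * W;
    mean.set_size(Cout); var.set_size(Cout); invstd.set_size(Cout);
    for (int c = 0; c < Cout; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const float* p = z[b].colptr(c);
        const size_t n = z[b].n_rows;
        for (size_t q = 0; q < n; ++q) {
          s += p[q];
          s2 += (double)p[q] * p[q];
        }
      }
      const double m = s / N;
      const double v = std::max(0.0, s2 / N - m * m);
      mean(c) = (float)m;
      var(c) = (float)v;
      invstd(c) = (float)(1.0 / std::sqrt(v + eps));
    }
    xhat.resize(B); aout.resize(B);
    const frowvec mr = mean.t(), ir = invstd.t(), gr = g.t(), br = be.t();
    for (int b = 0; b < B; ++b) {
      z[b].each_row() -= mr;
      z[b].each_row() %= ir;
      xhat[b] = z[b];
      z[b].each_row() %= gr;
      z[b].each_row() += br;
      relu_inplace(z[b]);
      aout[b] = std::move(z[b]);
    }
    return aout;
  }

  fmat forward_eval(const fmat& in, int H_, int W_, const fvec& rm,
                    const fvec& rv, double eps, Workspace& ws) {
    fmat cols = ws.mat((arma::uword)H_ * W_, Wt.n_rows);
    im2col3(in, H_, W_, cols);
    fmat z = cols * Wt;
    const int Cout = Wt.n_cols;
    frowvec ir(Cout);
    for (int c = 0; c < Cout; ++c)
      ir(c) = (float)(1.0 / std::sqrt((double)rv(c) + eps));
    z.each_row() -= rm.t();
    z.each_row() %= ir;
    z.each_row() %= g.t();
    z.each_row() += be.t();
    relu_inplace(z);
    return z;
  }

  // dA: gradient w.r.t. aout (consumed); in: the forward input.
  // Returns the gradient w.r.t. the input, unless want_dx is false.
  // The input gradient of a zero-padded same convolution is itself a same
  // convolution of the upstream gradient with the spatially flipped,
  // channel-transposed kernel, which keeps every gemm in the wide-K shape
  // BLAS likes.
  std::vector<fmat> backward(std::vector<fmat>& dA, Workspace& ws2,
                             bool want_dx = true) {
    const int B = dA.size(), Cout = Wt.n_cols, Cin = Wt.n_rows / 9;
    const double N = (double)B * H * W;
    fmat Wf;
    if (want_dx) {
      Wf.set_size(9 * Cout, Cin);
      for (int k = 0; k < 9; ++k)
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wf((size_t)k * Cout + co, ci) = Wt((size_t)(8 - k) * Cin + ci, co);
    }
    dg.zeros(Cout); dbe.zeros(Cout);
    for (int b = 0; b < B; ++b) {
      // ReLU mask, then the BN reductions
      const float* a = aout[b].memptr();
      float* d = dA[b].memptr();
      const size_t n = dA[b].n_elem;
      for (size_t q = 0; q < n; ++q)
        if (a[q] <= 0.0f) d[q] = 0.0f;
      for (int c = 0; c < Cout; ++c) {
        const float* dc = dA[b].colptr(c);
        const float* xh = xhat[b].colptr(c);
        double sg = 0, sb = 0;
        const size_t nr = dA[b].n_rows;
        for (size_t q = 0; q < nr; ++q) {
          sg += (double)dc[q] * xh[q];
          sb += dc[q];
        }
        dg(c) += (float)sg;
        dbe(c) += (float)sb;
      }
    }
    dW.zeros(Wt.n_rows, Cout);
    std::vector<fmat> dX(want_dx ? B : 0);
    const frowvec gr = g.t(), ir = invstd.t();
    for (int b = 0; b < B; ++b) {
      fmat dz = std::move(dA[b]);
      dz.each_row() %= gr;  // dxhat
      for (int c = 0; c < Cout; ++c) {
        const float a = (float)((double)dbe(c) * g(c) / N);
        const float bc = (float)((double)dg(c) * g(c) / N);
        float* p = dz.colptr(c);
        const float* xh = xhat[b].colptr(c);
        const size_t nr = dz.n_rows;
        for (size_t q = 0; q < nr; ++q) p[q] -= a + bc * xh[q];
      }
      dz.each_row() %= ir;
      dW += cols_cache[b].t() * dz;
      if (want_dx) {
        fmat cols2 = ws2.mat(dz.n_rows, (arma::uword)9 * Cout);
        im2col3(dz, H, W, cols2);
        dX[b] = cols2 * Wf;
      }
    }
    return dX;
  }
};

struct Net {
  ConvBN blk[10];
  fvec Wh;   // 1x1 head weights, length C10
  float bh;
  void load(const List& params) {
    for (int l = 0; l < 10; ++l) {
      std::string i = std::to_string(l + 1);
      blk[l].Wt = as_f(params["W" + i]);
      blk[l].g = as_fv(params["g" + i]);
      blk[l].be = as_fv(params["be" + i]);
    }
    Wh = as_fv(params["Wh"]);
    bh = (float)as<double>(params["bh"]);
  }
};

// spatial plan for one forward pass starting at (H0, W0):
// blocks 1-2 @H0 -> up -> 3-4 @2H0 -> up -> 5-6 @4H0 -> pool+concat(b4)
// -> 7-8 @2H0 -> pool+concat(b2) -> 9-10 @H0 -> 1x1 head + ReLU

// [[Rcpp::export]]
NumericMatrix net_forward_cpp(List params, List running, NumericVector x,
                              double eps = 1e-5) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) stop("input tile must be an H x W x C array");
  const int H = dims[0], W = dims[1], C = dims[2];
  fmat a((arma::uword)H * W, C);
  {
    const double* p = x.begin();
    for (int c = 0; c < C; ++c)
      for (size_t q = 0; q < (size_t)H * W; ++q)
        a(q, c) = (float)p[q + (size_t)c * H * W];
  }
  Net net;
  net.load(params);
  Workspace ws;
  auto rm = [&](int l) { return as_fv(running["rm" + std::to_string(l + 1)]); };
  auto rv = [&](int l) { return as_fv(running["rv" + std::to_string(l + 1)]); };

  fmat a1 = net.blk[0].forward_eval(a, H, W, rm(0), rv(0), eps, ws);
  fmat a2 = net.blk[1].forward_eval(a1, H, W, rm(1), rv(1), eps, ws);
  fmat u1 = upsample2(a2, H, W);
  fmat a3 = net.blk[2].forward_eval(u1, 2 * H, 2 * W, rm(2), rv(2), eps, ws);
  fmat a4 = net.blk[3].forward_eval(a3, 2 * H, 2 * W, rm(3), rv(3), eps, ws);
  fmat u2 = upsample2(a4, 2 * H, 2 * W);
  fmat a5 = net.blk[4].forward_eval(u2, 4 * H, 4 * W, rm(4), rv(4), eps, ws);
  fmat a6 = net.blk[5].forward_eval(a5, 4 * H, 4 * W, rm(5), rv(5), eps, ws);
  umat am1, am2;
  fmat c1 = arma::join_rows(maxpool2(a6, 4 * H, 4 * W, am1), a4);
  fmat a7 = net.blk[6].forward_eval(c1, 2 * H, 2 * W, rm(6), rv(6), eps, ws);
  fmat a8 = net.blk[7].forward_eval(a7, 2 * H, 2 * W, rm(7), rv(7), eps, ws);
  fmat c2 = arma::join_rows(maxpool2(a8, 2 * H, 2 * W, am2), a2);
  fmat a9 = net.blk[8].forward_eval(c2, H, W, rm(8), rv(8), eps, ws);
  fmat a10 = net.blk[9].forward_eval(a9, H, W, rm(9), rv(9), eps, ws);
  fvec out = a10 * net.Wh + net.bh;
  NumericMatrix res(H, W);
  for (size_t q = 0; q < (size_t)H * W; ++q)
    res[q] = out(q) > 0.0f ? out(q) : 0.0;
  return res;
}

// One training evaluation: forward in training mode (batch statistics),
// MSE loss, full backward; returns loss, parameter gradients and updated
// batch-norm running statistics.
// [[Rcpp::export]]
List net_grad_cpp(List params, List running, List xs, List ys,
                  double momentum = 0.1, double eps = 1e-5,
                  bool want_grads = true) {
  const int B = xs.size();
  if (B < 1 || ys.size() != B) stop("batch inputs and labels must match");
  Net net;
  net.load(params);
  Workspace ws, ws2;

  int H = 0, W = 0;
  std::vector<fmat> a(B), lab(B);
  for (int b = 0; b < B; ++b) {
    NumericVector x = xs[b];
    IntegerVector dims = x.attr("dim");
    if (dims.size() != 3) stop("each tile must be an H x W x C array");
    if (b == 0) { H = dims[0]; W = dims[1]; }
    else if (dims[0] != H || dims[1] != W) stop("tiles differ in size");
    const int C = dims[2];
    a[b].set_size((arma::uword)H * W, C);
    const double* p = x.begin();
    for (int c = 0; c < C; ++c)
      for (size_t q = 0; q < (size_t)H * W; ++q)
        a[b](q, c) = (float)p[q + (size_t)c * H * W];
    NumericMatrix ym = ys[b];
    if (ym.nrow() != H || ym.ncol() != W) stop("label size mismatch");
    lab[b].set_size((arma::uword)H * W, 1);
    for (size_t q = 0; q < (size_t)H * W; ++q) lab[b](q, 0) = (float)ym[q];
  }

  const std::vector<fmat>& a1v = net.blk[0].forward_train(a, H, W, eps, ws);
  const std::vector<fmat>& a2v = net.blk[1].forward_train(a1v, H, W, eps, ws);
  std::vector<fmat> u1(B);
  for (int b = 0; b < B; ++b) u1[b] = upsample2(a2v[b], H, W);
  const std::vector<fmat>& a3v =
      net.blk[2].forward_train(u1, 2 * H, 2 * W, eps, ws);
  const std::vector<fmat>& a4v =
      net.blk[3].forward_train(a3v, 2 * H, 2 * W, eps, ws);
  std::vector<fmat> u2(B);
  for (int b = 0; b < B; ++b) u2[b] = upsample2(a4v[b], 2 * H, 2 * W);
  const std::vector<fmat>& a5v =
      net.blk[4].forward_train(u2, 4 * H, 4 * W, eps, ws);
  const std::vector<fmat>& a6v =
      net.blk[5].forward_train(a5v, 4 * H, 4 * W, eps, ws);
  std::vector<umat> am1(B), am2(B);
  std::vector<fmat> c1(B);
  for (int b = 0; b < B; ++b)
    c1[b] = arma::join_rows(maxpool2(a6v[b], 4 * H, 4 * W, am1[b]), a4v[b]);
  const std::vector<fmat>& a7v =
      net.blk[6].forward_train(c1, 2 * H, 2 * W, eps, ws);
  const std::vector<fmat>& a8v =
      net.blk[7].forward_train(a7v, 2 * H, 2 * W, eps, ws);
  std::vector<fmat> c2(B);
  for (int b = 0; b < B; ++b)
    c2[b] = arma::join_rows(maxpool2(a8v[b], 2 * H, 2 * W, am2[b]), a2v[b]);
  const std::vector<fmat>& a9v = net.blk[8].forward_train(c2, H, W, eps, ws);
  const std::vector<fmat>& a10v =
      net.blk[9].forward_train(a9v, H, W, eps, ws);

  const int C6 = net.blk[5].Wt.n_cols;   // channels entering concat 1
  const int C8 = net.blk[7].Wt.n_cols;   // channels entering concat 2
  std::vector<fmat> out(B);
  double loss = 0.0;
  const double N = (double)B * H * W;
  for (int b = 0; b < B; ++b) {
    fvec o = a10v[b] * net.Wh + net.bh;
    float* po0 = o.memptr();
    for (arma::uword q = 0; q < o.n_elem; ++q)
      if (po0[q] < 0.0f) po0[q] = 0.0f;
    out[b] = o;
    const float* po = out[b].memptr();
    const float* pl = lab[b].memptr();
    for (size_t q = 0; q < (size_t)H * W; ++q) {
      const double d = (double)po[q] - pl[q];
      loss += d * d;
    }
  }
  loss /= N;

  List res;
  res["loss"] = loss;

  // running-statistics update (training-mode side effect)
  List newrun = clone(running);
  for (int l = 0; l < 10; ++l) {
    std::string i = std::to_string(l + 1);
    fvec rm = as_fv(running["rm" + i]), rv = as_fv(running["rv" + i]);
    rm = (1.0f - (float)momentum) * rm + (float)momentum * net.blk[l].mean;
    rv = (1.0f - (float)momentum) * rv + (float)momentum * net.blk[l].var;
    newrun["rm" + i] = to_Rv(rm);
    newrun["rv" + i] = to_Rv(rv);
  }
  res["running"] = newrun;
  if (!want_grads) return res;

  // backward
  fvec dWh(net.Wh.n_elem, arma::fill::zeros);
  double dbh = 0.0;
  std::vector<fmat> d10(B);
  for (int b = 0; b < B; ++b) {
    fvec dout = 2.0f / (float)N * (out[b] - lab[b].col(0));
    for (arma::uword q = 0; q < dout.n_elem; ++q)
      if (out[b](q, 0) <= 0.0f) dout(q) = 0.0f;   // head ReLU
    dWh += a10v[b].t() * dout;
    dbh += arma::accu(arma::conv_to<arma::vec>::from(dout));
    d10[b] = dout * net.Wh.t();
  }
  std::vector<fmat> d9 = net.blk[9].backward(d10, ws2);
  std::vector<fmat> dc2 = net.blk[8].backward(d9, ws2);
  std::vector<fmat> d8(B), dskip1(B);
  for (int b = 0; b < B; ++b) {
    d8[b] = maxpool2_back(dc2[b].cols(0, C8 - 1), am2[b], 2 * H, 2 * W);
    dskip1[b] = dc2[b].cols(C8, dc2[b].n_cols - 1);  // -> a2
  }
  std::vector<fmat> d7 = net.blk[7].backward(d8, ws2);
  std::vector<fmat> dc1 = net.blk[6].backward(d7, ws2);
  std::vector<fmat> d6(B), dskip2(B);
  for (int b = 0; b < B; ++b) {
    d6[b] = maxpool2_back(dc1[b].cols(0, C6 - 1), am1[b], 4 * H, 4 * W);
    dskip2[b] = dc1[b].cols(C6, dc1[b].n_cols - 1);  // -> a4
  }
  std::vector<fmat> d5 = net.blk[5].backward(d6, ws2);
  std::vector<fmat> du2 = net.blk[4].backward(d5, ws2);
  std::vector<fmat> d4(B);
  for (int b = 0; b < B; ++b)
    d4[b] = upsample2_back(du2[b], 2 * H, 2 * W) + dskip2[b];
  std::vector<fmat> d3 = net.blk[3].backward(d4, ws2);
  std::vector<fmat> du1 = net.blk[2].backward(d3, ws2);
  std::vector<fmat> d2(B);
  for (int b = 0; b < B; ++b)
    d2[b] = upsample2_back(du1[b], H, W) + dskip1[b];
  std::vector<fmat> d1 = net.blk[1].backward(d2, ws2);
  net.blk[0].backward(d1, ws2, false);  // input gradient not needed

  List grads;
  for (int l = 0; l < 10; ++l) {
    std::string i = std::to_string(l + 1);
    grads["W" + i] = to_R(net.blk[l].dW);
    grads["g" + i] = to_Rv(net.blk[l].dg);
    grads["be" + i] = to_Rv(net.blk[l].dbe);
  }
  grads["Wh"] = to_Rv(dWh);
  grads["bh"] = dbh;
  res["grads"] = grads;
  return res;
}

// ---------------------------------------------------------------------------
// Persistent trainer: keeps parameters, Adam moments, batch-norm running
// statistics and all large buffers alive across steps so the training loop
// is bandwidth-bound rather than allocator-bound. Exposed to R as an
// external pointer; the R fit loop drives batching, validation and
// checkpointing.

struct AdamVar {
  fmat m, v;
  void init(arma::uword r, arma::uword c) {
    m.zeros(r, c);
    v.zeros(r, c);
  }
};

static void adam_update(fmat& p, const fmat& g, AdamVar& s, float lr,
                        float b1, float b2, float eps, double t) {
  const float c1 = (float)(1.0 / (1.0 - std::pow((double)b1, t)));
  const float c2 = (float)(1.0 / (1.0 - std::pow((double)b2, t)));
  float* pp = p.memptr();
  const float* pg = g.memptr();
  float* pm = s.m.memptr();
  float* pv = s.v.memptr();
  const size_t n = p.n_elem;
  for (size_t q = 0; q < n; ++q) {
    pm[q] = b1 * pm[q] + (1.0f - b1) * pg[q];
    pv[q] = b2 * pv[q] + (1.0f - b2) * pg[q] * pg[q];
    pp[q] -= lr * (pm[q] * c1) / (std::sqrt(pv[q] * c2) + eps);
  }
}

struct Trainer {
  Net net;
  fvec rm[10], rv[10];
  AdamVar aW[10], ag[10], abe[10], aWh;
  float mbh = 0.0f, vbh = 0.0f;
  Workspace ws, ws2;
  long t = 0;

  void init(const List& params, const List& running) {
    net.load(params);
    for (int l = 0; l < 10; ++l) {
      std::string i = std::to_string(l + 1);
      rm[l] = as_fv(running["rm" + i]);
      rv[l] = as_fv(running["rv" + i]);
      aW[l].init(net.blk[l].Wt.n_rows, net.blk[l].Wt.n_cols);
      ag[l].init(net.blk[l].g.n_elem, 1);
      abe[l].init(net.blk[l].be.n_elem, 1);
    }
    aWh.init(net.Wh.n_elem, 1);
  }

  double step(const std::vector<fmat>& a0, const std::vector<fmat>& lab,
              int H, int W, float lr, float b1, float b2, float eps_adam,
              float momentum, double eps_bn) {
    const int B = a0.size();
    const std::vector<fmat>& a1v =
        net.blk[0].forward_train(a0, H, W, eps_bn, ws);
    const std::vector<fmat>& a2v =
        net.blk[1].forward_train(a1v, H, W, eps_bn, ws);
    std::vector<fmat> u1(B);
    for (int b = 0; b < B; ++b) u1[b] = upsample2(a2v[b], H, W);
    const std::vector<fmat>& a3v =
        net.blk[2].forward_train(u1, 2 * H, 2 * W, eps_bn, ws);
    const std::vector<fmat>& a4v =
        net.blk[3].forward_train(a3v, 2 * H, 2 * W, eps_bn, ws);
    std::vector<fmat> u2(B);
    for (int b = 0; b < B; ++b) u2[b] = upsample2(a4v[b], 2 * H, 2 * W);
    const std::vector<fmat>& a5v =
        net.blk[4].forward_train(u2, 4 * H, 4 * W, eps_bn, ws);
    const std::vector<fmat>& a6v =
        net.blk[5].forward_train(a5v, 4 * H, 4 * W, eps_bn, ws);
    std::vector<umat> am1(B), am2(B);
    std::vector<fmat> c1(B);
    for (int b = 0; b < B; ++b)
      c1[b] = arma::join_rows(maxpool2(a6v[b], 4 * H, 4 * W, am1[b]), a4v[b]);
    const std::vector<fmat>& a7v =
        net.blk[6].forward_train(c1, 2 * H, 2 * W, eps_bn, ws);
    const std::vector<fmat>& a8v =
        net.blk[7].forward_train(a7v, 2 * H, 2 * W, eps_bn, ws);
    std::vector<fmat> c2(B);
    for (int b = 0; b < B; ++b)
      c2[b] = arma::join_rows(maxpool2(a8v[b], 2 * H, 2 * W, am2[b]), a2v[b]);
    const std::vector<fmat>& a9v =
        net.blk[8].forward_train(c2, H, W, eps_bn, ws);
    const std::vector<fmat>& a10v =
        net.blk[9].forward_train(a9v, H, W, eps_bn, ws);

    const int C6 = net.blk[5].Wt.n_cols;
    const int C8 = net.blk[7].Wt.n_cols;
    std::vector<fmat> out(B);
    double loss = 0.0;
    const double N = (double)B * H * W;
    for (int b = 0; b < B; ++b) {
      fvec o = a10v[b] * net.Wh + net.bh;
      float* po0 = o.memptr();
      for (arma::uword q = 0; q < o.n_elem; ++q)
        if (po0[q] < 0.0f) po0[q] = 0.0f;
      out[b] = o;
      const float* po = out[b].memptr();
      const float* pl = lab[b].memptr();
      for (size_t q = 0; q < (size_t)H * W; ++q) {
        const double d = (double)po[q] - pl[q];
        loss += d * d;
      }
    }
    loss /= N;
    if (!std::isfinite(loss)) return loss;  // caller aborts; no update

    for (int l = 0; l < 10; ++l) {
      rm[l] = (1.0f - momentum) * rm[l] + momentum * net.blk[l].mean;
      rv[l] = (1.0f - momentum) * rv[l] + momentum * net.blk[l].var;
    }

    fvec dWh(net.Wh.n_elem, arma::fill::zeros);
    double dbh = 0.0;
    std::vector<fmat> d10(B);
    for (int b = 0; b < B; ++b) {
      fvec dout = 2.0f / (float)N * (out[b] - lab[b].col(0));
      for (arma::uword q = 0; q < dout.n_elem; ++q)
        if (out[b](q, 0) <= 0.0f) dout(q) = 0.0f;
      dWh += a10v[b].t() * dout;
      dbh += arma::accu(arma::conv_to<arma::vec>::from(dout));
      d10[b] = dout * net.Wh.t();
    }
    std::vector<fmat> d9 = net.blk[9].backward(d10, ws2);
    std::vector<fmat> dc2 = net.blk[8].backward(d9, ws2);
    std::vector<fmat> d8(B), dskip1(B);
    for (int b = 0; b < B; ++b) {
      d8[b] = maxpool2_back(dc2[b].cols(0, C8 - 1), am2[b], 2 * H, 2 * W);
      dskip1[b] = dc2[b].cols(C8, dc2[b].n_cols - 1);
    }
    std::vector<fmat> d7 = net.blk[7].backward(d8, ws2);
    std::vector<fmat> dc1 = net.blk[6].backward(d7, ws2);
    std::vector<fmat> d6(B), dskip2(B);
    for (int b = 0; b < B; ++b) {
      d6[b] = maxpool2_back(dc1[b].cols(0, C6 - 1), am1[b], 4 * H, 4 * W);
      dskip2[b] = dc1[b].cols(C6, dc1[b].n_cols - 1);
    }
    std::vector<fmat> d5 = net.blk[5].backward(d6, ws2);
    std::vector<fmat> du2 = net.blk[4].backward(d5, ws2);
    std::vector<fmat> d4(B);
    for (int b = 0; b < B; ++b)
      d4[b] = upsample2_back(du2[b], 2 * H, 2 * W) + dskip2[b];
    std::vector<fmat> d3 = net.blk[3].backward(d4, ws2);
    std::vector<fmat> du1 = net.blk[2].backward(d3, ws2);
    std::vector<fmat> d2(B);
    for (int b = 0; b < B; ++b)
      d2[b] = upsample2_back(du1[b], H, W) + dskip1[b];
    std::vector<fmat> d1 = net.blk[1].backward(d2, ws2);
    net.blk[0].backward(d1, ws2, false);

    ++t;
    for (int l = 0; l < 10; ++l) {
      adam_update(net.blk[l].Wt, net.blk[l].dW, aW[l], lr, b1, b2, eps_adam,
                  (double)t);
      fmat gg(net.blk[l].dg.memptr(), net.blk[l].dg.n_elem, 1, false, true);
      fmat gp(net.blk[l].g.memptr(), net.blk[l].g.n_elem, 1, false, true);
      adam_update(gp, gg, ag[l], lr, b1, b2, eps_adam, (double)t);
      fmat bg(net.blk[l].dbe.memptr(), net.blk[l].dbe.n_elem, 1, false, true);
      fmat bp(net.blk[l].be.memptr(), net.blk[l].be.n_elem, 1, false, true);
      adam_update(bp, bg, abe[l], lr, b1, b2, eps_adam, (double)t);
    }
    {
      fmat hg(dWh.memptr(), dWh.n_elem, 1, false, true);
      fmat hp(net.Wh.memptr(), net.Wh.n_elem, 1, false, true);
      adam_update(hp, hg, aWh, lr, b1, b2, eps_adam, (double)t);
      const float c1c = (float)(1.0 / (1.0 - std::pow((double)b1, (double)t)));
      const float c2c = (float)(1.0 / (1.0 - std::pow((double)b2, (double)t)));
      mbh = b1 * mbh + (1.0f - b1) * (float)dbh;
      vbh = b2 * vbh + (1.0f - b2) * (float)(dbh * dbh);
      net.bh -= lr * (mbh * c1c) / (std::sqrt(vbh * c2c) + eps_adam);
    }
    return loss;
  }
};

// [[Rcpp::export]]
SEXP net_trainer_create(List params, List running) {
  Rcpp::XPtr<Trainer> ptr(new Trainer(), true);
  ptr->init(params, running);
  return ptr;
}

// [[Rcpp::export]]
double net_trainer_step(SEXP trainer, List xs, List ys, double lr,
                        double beta1, double beta2, double eps_adam,
                        double momentum = 0.1, double eps_bn = 1e-5) {
  Rcpp::XPtr<Trainer> ptr(trainer);
  const int B = xs.size();
  if (B < 1 || ys.size() != B) stop("batch inputs and labels must match");
  int H = 0, W = 0;
  std::vector<fmat> a(B), lab(B);
  for (int b = 0; b < B; ++b) {
    NumericVector x = xs[b];
    IntegerVector dims = x.attr("dim");
    if (dims.size() != 3) stop("each tile must be an H x W x C array");
    if (b == 0) { H = dims[0]; W = dims[1]; }
    else if (dims[0] != H || dims[1] != W) stop("tiles differ in size");
    const int C = dims[2];
    a[b].set_size((arma::uword)H * W, C);
    const double* p = x.begin();
    for (int c = 0; c < C; ++c)
      for (size_t q = 0; q < (size_t)H * W; ++q)
        a[b](q, c) = (float)p[q + (size_t)c * H * W];
    NumericMatrix ym = ys[b];
    if (ym.nrow() != H || ym.ncol() != W) stop("label size mismatch");
    lab[b].set_size((arma::uword)H * W, 1);
    for (size_t q = 0; q < (size_t)H * W; ++q) lab[b](q, 0) = (float)ym[q];
  }
  return ptr->step(a, lab, H, W, (float)lr, (float)beta1, (float)beta2,
                   (float)eps_adam, (float)momentum, eps_bn);
}

// [[Rcpp::export]]
List net_trainer_state(SEXP trainer) {
  Rcpp::XPtr<Trainer> ptr(trainer);
  List params, running;
  for (int l = 0; l < 10; ++l) {
    std::string i = std::to_string(l + 1);
    params["W" + i] = to_R(ptr->net.blk[l].Wt);
    params["g" + i] = to_Rv(ptr->net.blk[l].g);
    params["be" + i] = to_Rv(ptr->net.blk[l].be);
    running["rm" + i] = to_Rv(ptr->rm[l]);
    running["rv" + i] = to_Rv(ptr->rv[l]);
  }
  params["Wh"] = to_Rv(ptr->net.Wh);
  params["bh"] = (double)ptr->net.bh;
  return List::create(Named("params") = params, Named("running") = running);
}
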