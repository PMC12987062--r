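// Low-level numerical kernels: 3D convolution (im2col + GEMM), anisotropic
// max-pooling / nearest upsampling, trilinear field sampling, a separable
// squared Euclidean distance transform with physical voxel spacing, and
// 6-connected component labelling.
//
// Array layout convention: 4D fields are stored channel-fastest as
// (C, D, H, W) in column-major order, i.e. linear index
//   c + C*(d + D*(h + H*w)).
// 3D grids are (D, H, W), index d + D*(h + H*w).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword lin4(arma::uword c, arma::uword d, arma::uword h,
                               arma::uword w, arma::uword C, arma::uword D,
                               arma::uword H) {
  return c + C * (d + D * (h + H * w));
}

// Convolution as a sum of shifted GEMMs: for each kernel offset o the
// contribution is W_o * shift_o(x), with shift_o gathering the input
// columns displaced by the offset (zero at borders). Avoids materializing
// the full im2col matrix. Weight layout: Wm is (Cout x C*kd*kh*kw) with
// column blocks of width C per offset, offsets ordered kd-fastest, then
// kh, then kw.

// Gather shift_o(x) into a pre-allocated C x N buffer.
static void shiftGather(const double* x, double* out, int C, int D, int H,
                        int W, int od, int oh, int ow) {
  const size_t colD = (size_t)C * D;
  const int dlo = std::max(0, -od), dhi = std::min(D - 1, D - 1 - od);
  for (int w = 0; w < W; ++w) {
    const int sw = w + ow;
    for (int h = 0; h < H; ++h) {
      const int sh = h + oh;
      double* dst = out + (size_t)C * D * (h + (size_t)H * w);
      if (sw < 0 || sw >= W || sh < 0 || sh >= H || dlo > dhi) {
        std::fill(dst, dst + colD, 0.0);
        continue;
      }
      if (dlo > 0) std::fill(dst, dst + (size_t)C * dlo, 0.0);
      const double* src = x + lin4(0, dlo + od, sh, sw, C, D, H);
      std::copy(src, src + (size_t)C * (dhi - dlo + 1),
                dst + (size_t)C * dlo);
      if (dhi < D - 1)
        std::fill(dst + (size_t)C * (dhi + 1), dst + colD, 0.0);
    }
  }
}

// Scatter-add the reverse mapping: gx[source] += g[dest].
static void shiftScatterAdd(const double* g, double* gx, int C, int D,
                            int H, int W, int od, int oh, int ow) {
  const int dlo = std::max(0, -od), dhi = std::min(D - 1, D - 1 - od);
  for (int w = 0; w < W; ++w) {
    const int sw = w + ow;
    if (sw < 0 || sw >= W) continue;
    for (int h = 0; h < H; ++h) {
      const int sh = h + oh;
      if (sh < 0 || sh >= H || dlo > dhi) continue;
      const double* src = g + (size_t)C * (dlo + (size_t)D *
                                           (h + (size_t)H * w));
      double* dst = gx + lin4(0, dlo + od, sh, sw, C, D, H);
      const size_t len = (size_t)C * (dhi - dlo + 1);
      for (size_t i = 0; i < len; ++i) dst[i] += src[i];
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector xdim,
                             const arma::mat& Wm, const arma::vec& b,
                             IntegerVector k) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  const arma::uword N = (arma::uword)D * H * W;
  const int Cout = Wm.n_rows;
  NumericVector out((arma::uword)Cout * N);
  arma::mat y(out.begin(), Cout, N, false);
  arma::mat xs(C, N, arma::fill::none);
  int oidx = 0;
  for (int kwi = 0; kwi < kw; ++kwi)
    for (int khi = 0; khi < kh; ++khi)
      for (int kdi = 0; kdi < kd; ++kdi, ++oidx) {
        shiftGather(x.begin(), xs.memptr(), C, D, H, W,
                    kdi - pd, khi - ph, kwi - pw);
        const arma::mat Wo = Wm.cols((arma::uword)C * oidx,
                                     (arma::uword)C * oidx + C - 1);
        if (oidx == 0) y = Wo * xs; else y += Wo * xs;
      }
  y.each_col() += b;
  out.attr("dim") = IntegerVector::create(Cout, D, H, W);
  return out;
}

// Returns grad_x (same dim as x), grad_W, grad_b. Set needGx = false for
// the first layer of a network, where the input gradient is unused.
// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, IntegerVector xdim,
                     const arma::mat& Wm, NumericVector gy,
                     IntegerVector k, bool needGx = true) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  const arma::uword N = (arma::uword)D * H * W;
  const int Cout = Wm.n_rows;
  arma::mat gym(gy.begin(), Cout, N, false);

  arma::mat gW(Cout, (arma::uword)C * kd * kh * kw, arma::fill::none);
  arma::vec gb = arma::sum(gym, 1);
  NumericVector gx(needGx ? x.size() : R_xlen_t(0));
  arma::mat xs(C, N, arma::fill::none);
  arma::mat gxs;
  if (needGx) gxs.set_size(C, N);
  int oidx = 0;
  for (int kwi = 0; kwi < kw; ++kwi)
    for (int khi = 0; khi < kh; ++khi)
      for (int kdi = 0; kdi < kd; ++kdi, ++oidx) {
        const int od = kdi - pd, oh = khi - ph, ow = kwi - pw;
        shiftGather(x.begin(), xs.memptr(), C, D, H, W, od, oh, ow);
        gW.cols((arma::uword)C * oidx, (arma::uword)C * oidx + C - 1) =
          gym * xs.t();
        if (needGx) {
          const arma::mat Wo = Wm.cols((arma::uword)C * oidx,
                                       (arma::uword)C * oidx + C - 1);
          gxs = Wo.t() * gym;
          shiftScatterAdd(gxs.memptr(), gx.begin(), C, D, H, W, od, oh, ow);
        }
      }
  if (needGx) gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = gb);
}

// In-plane max pooling, kernel = stride = (1, f, f). H and W must divide f.
// Returns pooled field and 1-based argmax indices into x.
// [[Rcpp::export(name = ".maxpool_hw")]]
List maxpool_hw(NumericVector x, IntegerVector xdim, int f) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H / f, Wo = W / f;
  NumericVector y((arma::uword)C * D * Ho * Wo);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int d = 0; d < D; ++d)
        for (int c = 0; c < C; ++c) {
          double best = -INFINITY; arma::uword besti = 0;
          for (int dw = 0; dw < f; ++dw)
            for (int dh = 0; dh < f; ++dh) {
              arma::uword q = lin4(c, d, ho * f + dh, wo * f + dw, C, D, H);
              if (xp[q] > best) { best = xp[q]; besti = q; }
            }
          arma::uword o = lin4(c, d, ho, wo, C, D, Ho);
          yp[o] = best; ip[o] = (int)(besti + 1);
        }
  y.attr("dim") = IntegerVector::create(C, D, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_hw_backward")]]
NumericVector maxpool_hw_backward(NumericVector gy, IntegerVector idx,
                                  IntegerVector xdim) {
  NumericVector gx((arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Nearest-neighbour in-plane upsampling by factor f (depth untouched).
// [[Rcpp::export(name = ".upsample_hw")]]
NumericVector upsample_hw(NumericVector x, IntegerVector xdim, int f) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y((arma::uword)C * D * Ho * Wo);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int d = 0; d < D; ++d) {
        const double* src = xp + lin4(0, d, ho / f, wo / f, C, D, H);
        double* dst = yp + lin4(0, d, ho, wo, C, D, Ho);
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  y.attr("dim") = IntegerVector::create(C, D, Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".upsample_hw_backward")]]
NumericVector upsample_hw_backward(NumericVector gy, IntegerVector ydim,
                                   int f) {
  const int C = ydim[0], D = ydim[1], Ho = ydim[2], Wo = ydim[3];
  const int H = Ho / f, W = Wo / f;
  NumericVector gx((arma::uword)C * D * H * W);
  const double* gp = gy.begin(); double* xp = gx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int d = 0; d < D; ++d) {
        const double* src = gp + lin4(0, d, ho, wo, C, D, Ho);
        double* dst = xp + lin4(0, d, ho / f, wo / f, C, D, H);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  return gx;
}

// Trilinear sampling of a (C, D, H, W) field at N normalized coordinates.
// coords is N x 3 with columns (x, y, z) in [-1, 1]; x indexes W, y indexes H,
// z indexes D. Centre-aligned convention: coordinate t on an axis of length n
// maps to continuous index (t + 1) / 2 * (n - 1); axes of length 1 map to 0.
// Returns N x C matrix of interpolated values.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericMatrix trilinear_sample(NumericVector field, IntegerVector fdim,
                               const arma::mat& coords) {
  const int C = fdim[0], D = fdim[1], H = fdim[2], W = fdim[3];
  const arma::uword N = coords.n_rows;
  NumericMatrix out(N, C);
  const double* fp = field.begin();
  for (arma::uword i = 0; i < N; ++i) {
    double tz = D > 1 ? (coords(i, 2) + 1.0) / 2.0 * (D - 1) : 0.0;
    double ty = H > 1 ? (coords(i, 1) + 1.0) / 2.0 * (H - 1) : 0.0;
    double tx = W > 1 ? (coords(i, 0) + 1.0) / 2.0 * (W - 1) : 0.0;
    tz = std::min(std::max(tz, 0.0), (double)(D - 1));
    ty = std::min(std::max(ty, 0.0), (double)(H - 1));
    tx = std::min(std::max(tx, 0.0), (double)(W - 1));
    const int z0 = (int)std::floor(tz), y0 = (int)std::floor(ty),
              x0 = (int)std::floor(tx);
    const int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1),
              x1 = std::min(x0 + 1, W - 1);
    const double fz = tz - z0, fy = ty - y0, fx = tx - x0;
    for (int c = 0; c < C; ++c) {
      const double v000 = fp[lin4(c, z0, y0, x0, C, D, H)];
      const double v100 = fp[lin4(c, z1, y0, x0, C, D, H)];
      const double v010 = fp[lin4(c, z0, y1, x0, C, D, H)];
      const double v110 = fp[lin4(c, z1, y1, x0, C, D, H)];
      const double v001 = fp[lin4(c, z0, y0, x1, C, D, H)];
      const double v101 = fp[lin4(c, z1, y0, x1, C, D, H)];
      const double v011 = fp[lin4(c, z0, y1, x1, C, D, H)];
      const double v111 = fp[lin4(c, z1, y1, x1, C, D, H)];
      const double c00 = v000 * (1 - fz) + v100 * fz;
      const double c10 = v010 * (1 - fz) + v110 * fz;
      const double c01 = v001 * (1 - fz) + v101 * fz;
      const double c11 = v011 * (1 - fz) + v111 * fz;
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      out(i, c) = c0 * (1 - fx) + c1 * fx;
    }
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s: d(p) = min_q ((p - q) s)^2 + f(q).
// "Infinity" for absent sites must stay finite: an infinite f makes the
// parabola intersection degenerate and breaks the envelope recursion.
static const double DT_HUGE = 1e20;

static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -DT_HUGE; z[1] = DT_HUGE;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sI;
    while (true) {
      sI = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
           (2.0 * s2 * (q - v[k]));
      if (k > 0 && sI <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = sI; z[k + 1] = DT_HUGE;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel centre to the nearest TRUE voxel
// centre of `mask` (D, H, W), honouring anisotropic spacing (sz, sy, sx).
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector mdim,
                     NumericVector spacing) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const arma::uword n = (arma::uword)D * H * W;
  std::vector<double> f(n);
  for (arma::uword i = 0; i < n; ++i) f[i] = mask[i] ? 0.0 : DT_HUGE;
  std::vector<double> buf(std::max(std::max(D, H), W));
  std::vector<double> out(std::max(std::max(D, H), W));
  // pass along D (stride 1 within a column of fixed h, w)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* col = f.data() + (arma::uword)D * (h + (arma::uword)H * w);
      dt1d(col, out.data(), D, sz);
      std::copy(out.begin(), out.begin() + D, col);
    }
  // pass along H
  for (int w = 0; w < W; ++w)
    for (int d = 0; d < D; ++d) {
      for (int h = 0; h < H; ++h)
        buf[h] = f[d + (arma::uword)D * (h + (arma::uword)H * w)];
      dt1d(buf.data(), out.data(), H, sy);
      for (int h = 0; h < H; ++h)
        f[d + (arma::uword)D * (h + (arma::uword)H * w)] = out[h];
    }
  // pass along W
  for (int h = 0; h < H; ++h)
    for (int d = 0; d < D; ++d) {
      for (int w = 0; w < W; ++w)
        buf[w] = f[d + (arma::uword)D * (h + (arma::uword)H * w)];
      dt1d(buf.data(), out.data(), W, sx);
      for (int w = 0; w < W; ++w)
        f[d + (arma::uword)D * (h + (arma::uword)H * w)] = out[w];
    }
  NumericVector res(n);
  for (arma::uword i = 0; i < n; ++i) res[i] = std::sqrt(f[i]);
  res.attr("dim") = mdim;
  return res;
}

// 6-connected component labelling of a binary mask (D, H, W).
// Returns integer array of component ids (0 = background).
// [[Rcpp::export(name = ".cc6_label")]]
IntegerVector cc6_label(LogicalVector mask, IntegerVector mdim) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const arma::uword n = (arma::uword)D * H * W;
  IntegerVector lab(n);
  int next = 0;
  std::queue<arma::uword> q;
  const int dd[6] = { 1, -1, 0, 0, 0, 0 };
  const int dh[6] = { 0, 0, 1, -1, 0, 0 };
  const int dw[6] = { 0, 0, 0, 0, 1, -1 };
  for (arma::uword i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      arma::uword cur = q.front(); q.pop();
      const int d = cur % D, h = (cur / D) % H, w = cur / ((arma::uword)D * H);
      for (int m = 0; m < 6; ++m) {
        const int nd = d + dd[m], nh = h + dh[m], nw = w + dw[m];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
          continue;
        const arma::uword j = nd + (arma::uword)D * (nh + (arma::uword)H * nw);
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}
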