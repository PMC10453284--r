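// Low-level numeric kernels for the network layers.
//
// Tensor convention: R arrays with dim c(H, W, C, N), column-major, so the
// row index (h) is fastest.  Convolutions are stride-1 with symmetric zero
// padding `pad` (spatial size preserved for odd kernels with pad=(k-1)/2).
// Weights: dim c(k, k, C_in/groups, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `col` ((H*W) x (k*k*Cg)) from channels [c0, c0+Cg) of one sample
// plane `x` (H x W x C).  Column index j = dy + k*dx + k*k*c, matching the
// flattening of the first three weight dims.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int k, int pad, arma::mat& col) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cg; ++c) {
    const double* plane = x + (size_t)(c0 + c) * HW;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        double* dst = col.colptr((size_t)dy + (size_t)k * dx + (size_t)k * k * c);
        for (int w = 0; w < W; ++w) {
          int sw = w + dx - pad;
          double* d = dst + (size_t)w * H;
          if (sw < 0 || sw >= W) { std::fill(d, d + H, 0.0); continue; }
          const double* sp = plane + (size_t)sw * H;
          int h0 = std::max(0, pad - dy);
          int h1 = std::min(H, H + pad - dy);
          for (int h = 0;  h < h0; ++h) d[h] = 0.0;
          for (int h = h0; h < h1; ++h) d[h] = sp[h + dy - pad];
          for (int h = h1; h < H;  ++h) d[h] = 0.0;
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add `col` back into channels [c0, c0+Cg) of dx.
static void col2im(const arma::mat& col, double* dx, int H, int W,
                   int c0, int Cg, int k, int pad) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cg; ++c) {
    double* plane = dx + (size_t)(c0 + c) * HW;
    for (int dx_ = 0; dx_ < k; ++dx_) {
      for (int dy = 0; dy < k; ++dy) {
        const double* src = col.colptr((size_t)dy + (size_t)k * dx_ + (size_t)k * k * c);
        for (int w = 0; w < W; ++w) {
          int sw = w + dx_ - pad;
          if (sw < 0 || sw >= W) continue;
          double* sp = plane + (size_t)sw * H;
          const double* s = src + (size_t)w * H;
          int h0 = std::max(0, pad - dy);
          int h1 = std::min(H, H + pad - dy);
          for (int h = h0; h < h1; ++h) sp[h + dy - pad] += s[h];
        }
      }
    }
  }
}

static void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& b, int pad, int groups) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cg * groups) stop("input channels %d incompatible with %d groups of %d", C, groups, Cg);
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  const int Og = Cout / groups;
  const size_t HW = (size_t)H * W;

  NumericVector out(HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(HW, (size_t)k * k * Cg);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* on = out.begin() + (size_t)n * HW * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, k, pad, col);
      const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Og * k * k * Cg,
                         (size_t)k * k * Cg, Og, false, true);
      arma::mat om(on + (size_t)g * Og * HW, HW, Og, false, true);
      om = col * Wm;
      for (int o = 0; o < Og; ++o) om.col(o) += b[g * Og + o];
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& dout, int pad, int groups) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  const int Og = Cout / groups;
  const size_t HW = (size_t)H * W;

  NumericVector dx(x.size());  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat col(HW, (size_t)k * k * Cg);
  arma::mat dcol(HW, (size_t)k * k * Cg);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    const double* dn = dout.begin() + (size_t)n * HW * Cout;
    double* dxn = dx.begin() + (size_t)n * HW * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, k, pad, col);
      const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Og * k * k * Cg,
                         (size_t)k * k * Cg, Og, false, true);
      const arma::mat dm(const_cast<double*>(dn) + (size_t)g * Og * HW, HW, Og, false, true);
      arma::mat dWm(dw.begin() + (size_t)g * Og * k * k * Cg, (size_t)k * k * Cg, Og, false, true);
      dWm += col.t() * dm;
      for (int o = 0; o < Og; ++o) db[g * Og + o] += arma::accu(dm.col(o));
      dcol = dm * Wm.t();
      col2im(dcol, dxn, H, W, g * Cg, Cg, k, pad);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear index
// (0-based, within each H x W plane) of each maximum for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(const NumericVector& x) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims, got %dx%d", H, W);
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  NumericVector out(HW2 * C * N);
  IntegerVector idx(HW2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* plane = x.begin() + p * HW;
    double* o = out.begin() + p * HW2;
    int* ix = idx.begin() + p * HW2;
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        int base = 2 * h + H * 2 * w;
        int cand[4] = { base, base + 1, base + H, base + H + 1 };
        int best = cand[0];
        for (int j = 1; j < 4; ++j) if (plane[cand[j]] > plane[best]) best = cand[j];
        o[h + (size_t)H2 * w] = plane[best];
        ix[h + (size_t)H2 * w] = best;
      }
    }
  }
  return List::create(_["v"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(const NumericVector& dout, const IntegerVector& idx,
                           int H, int W) {
  int d[4]; get_dims4(dout, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* g = dout.begin() + p * HW2;
    const int* ix = idx.begin() + p * HW2;
    double* o = dx.begin() + p * HW;
    for (size_t q = 0; q < HW2; ++q) o[ix[q]] += g[q];
  }
  return dx;
}

// Bilinear x2 upsampling (align_corners = FALSE convention).
static void up2_coeffs(int Hout, int H, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& t) {
  i0.resize(Hout); i1.resize(Hout); t.resize(Hout);
  for (int o = 0; o < Hout; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double tt = s - f;
    int a = std::min(std::max(f, 0), H - 1);
    int b = std::min(std::max(f + 1, 0), H - 1);
    i0[o] = a; i1[o] = b; t[o] = tt;
  }
}

// [[Rcpp::export]]
NumericVector up2_fwd(const NumericVector& x) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = 2 * H, W2 = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  up2_coeffs(H2, H, h0, h1, th);
  up2_coeffs(W2, W, w0, w1, tw);
  NumericVector out((size_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* in = x.begin() + p * HW;
    double* o = out.begin() + p * HW2;
    for (int w = 0; w < W2; ++w) {
      const double* cA = in + (size_t)H * w0[w];
      const double* cB = in + (size_t)H * w1[w];
      double a = 1.0 - tw[w], bwt = tw[w];
      for (int h = 0; h < H2; ++h) {
        double top = a * cA[h0[h]] + bwt * cB[h0[h]];
        double bot = a * cA[h1[h]] + bwt * cB[h1[h]];
        o[h + (size_t)H2 * w] = (1.0 - th[h]) * top + th[h] * bot;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector up2_bwd(const NumericVector& dout, int H, int W) {
  int d[4]; get_dims4(dout, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  up2_coeffs(H2, H, h0, h1, th);
  up2_coeffs(W2, W, w0, w1, tw);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* g = dout.begin() + p * HW2;
    double* o = dx.begin() + p * HW;
    for (int w = 0; w < W2; ++w) {
      double a = 1.0 - tw[w], bwt = tw[w];
      for (int h = 0; h < H2; ++h) {
        double gg = g[h + (size_t)H2 * w];
        o[h0[h] + (size_t)H * w0[w]] += a * (1.0 - th[h]) * gg;
        o[h0[h] + (size_t)H * w1[w]] += bwt * (1.0 - th[h]) * gg;
        o[h1[h] + (size_t)H * w0[w]] += a * th[h] * gg;
        o[h1[h] + (size_t)H * w1[w]] += bwt * th[h] * gg;
      }
    }
  }
  return dx;
}

// Local attention aggregation: D(h,w,c,n) = sum_o A(h,w, o + k2*g(c), n) *
// V(h+dy-pad, w+dx-pad, c, n), offsets o = dy + k*dx over a k x k window,
// pad = (k-1)/2, zero outside the image.  g(c) = c / (C/groups).
// [[Rcpp::export]]
NumericVector local_attn_fwd(const NumericVector& a, const NumericVector& v,
                             int k, int groups) {
  int dv[4]; get_dims4(v, dv);
  const int H = dv[0], W = dv[1], C = dv[2], N = dv[3];
  int da[4]; get_dims4(a, da);
  const int k2 = k * k, pad = (k - 1) / 2, Cpg = C / groups;
  if (da[2] != groups * k2) stop("attention map has %d channels, expected %d", da[2], groups * k2);
  NumericVector out(v.size());
  out.attr("dim") = v.attr("dim");
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const int g = c / Cpg;
      const double* vp = v.begin() + HW * ((size_t)c + (size_t)C * n);
      double* op = out.begin() + HW * ((size_t)c + (size_t)C * n);
      for (int o = 0; o < k2; ++o) {
        const int dy = o % k - pad, dx = o / k - pad;
        const double* ap = a.begin() + HW * ((size_t)(o + k2 * g) + (size_t)groups * k2 * n);
        int wlo = std::max(0, -dx), whi = std::min(W, W - dx);
        int hlo = std::max(0, -dy), hhi = std::min(H, H - dy);
        for (int w = wlo; w < whi; ++w) {
          const double* vcol = vp + (size_t)H * (w + dx) + dy;
          const double* acol = ap + (size_t)H * w;
          double* ocol = op + (size_t)H * w;
          for (int h = hlo; h < hhi; ++h) ocol[h] += acol[h] * vcol[h];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List local_attn_bwd(const NumericVector& a, const NumericVector& v,
                    const NumericVector& dout, int k, int groups) {
  int dv[4]; get_dims4(v, dv);
  const int H = dv[0], W = dv[1], C = dv[2], N = dv[3];
  const int k2 = k * k, pad = (k - 1) / 2, Cpg = C / groups;
  NumericVector da(a.size()); da.attr("dim") = a.attr("dim");
  NumericVector dvx(v.size()); dvx.attr("dim") = v.attr("dim");
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const int g = c / Cpg;
      const double* vp = v.begin() + HW * ((size_t)c + (size_t)C * n);
      const double* gp = dout.begin() + HW * ((size_t)c + (size_t)C * n);
      double* dvp = dvx.begin() + HW * ((size_t)c + (size_t)C * n);
      for (int o = 0; o < k2; ++o) {
        const int dy = o % k - pad, dx = o / k - pad;
        const double* ap = a.begin() + HW * ((size_t)(o + k2 * g) + (size_t)groups * k2 * n);
        double* dap = da.begin() + HW * ((size_t)(o + k2 * g) + (size_t)groups * k2 * n);
        int wlo = std::max(0, -dx), whi = std::min(W, W - dx);
        int hlo = std::max(0, -dy), hhi = std::min(H, H - dy);
        for (int w = wlo; w < whi; ++w) {
          const double* vcol = vp + (size_t)H * (w + dx) + dy;
          double* dvcol = dvp + (size_t)H * (w + dx) + dy;
          const double* acol = ap + (size_t)H * w;
          double* dacol = dap + (size_t)H * w;
          const double* gcol = gp + (size_t)H * w;
          for (int h = hlo; h < hhi; ++h) {
            dacol[h] += gcol[h] * vcol[h];
            dvcol[h] += gcol[h] * acol[h];
          }
        }
      }
    }
  }
  return List::create(_["da"] = da, _["dv"] = dvx);
}

// ---- batch-norm helpers: per-channel reductions and affine broadcast ----

// [[Rcpp::export]]
NumericVector channel_mean(const NumericVector& x) {
  int d[4]; get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * ((size_t)c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += p[i];
      out[c] += s;
    }
  for (int c = 0; c < C; ++c) out[c] /= (double)HW * N;
  return out;
}

// per-channel mean of x*y over (H, W, N)
// [[Rcpp::export]]
NumericVector channel_dot(const NumericVector& x, const NumericVector& y) {
  int d[4]; get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * ((size_t)c + (size_t)C * n);
      const double* p = x.begin() + off;
      const double* q = y.begin() + off;
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += p[i] * q[i];
      out[c] += s;
    }
  for (int c = 0; c < C; ++c) out[c] /= (double)HW * N;
  return out;
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector scale_shift(const NumericVector& x, const NumericVector& a,
                          const NumericVector& b) {
  int d[4]; get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * ((size_t)c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* o = out.begin() + off;
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) o[i] = p[i] * ac + bc;
    }
  return out;
}

// Softmax over the k2 local offsets of an (H, W, groups*k2, N) logit tensor
// (offset index fastest within each group).
// [[Rcpp::export]]
NumericVector softmax_offsets_fwd(const NumericVector& x, int k2, int groups) {
  int d[4]; get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  if (C != k2 * groups) stop("bad attention channel count");
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  std::vector<const double*> in(k2);
  std::vector<double*> op(k2);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      for (int o = 0; o < k2; ++o) {
        const size_t off = HW * ((size_t)(o + k2 * g) + (size_t)C * n);
        in[o] = x.begin() + off;
        op[o] = out.begin() + off;
      }
      for (size_t i = 0; i < HW; ++i) {
        double m = in[0][i];
        for (int o = 1; o < k2; ++o) m = std::max(m, in[o][i]);
        double s = 0;
        for (int o = 0; o < k2; ++o) { double e = std::exp(in[o][i] - m); op[o][i] = e; s += e; }
        for (int o = 0; o < k2; ++o) op[o][i] /= s;
      }
    }
  return out;
}

// backward: dz_o = y_o * (g_o - sum_o' g_o' y_o')
// [[Rcpp::export]]
NumericVector softmax_offsets_bwd(const NumericVector& y, const NumericVector& g,
                                  int k2, int groups) {
  int d[4]; get_dims4(y, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(y.size());
  out.attr("dim") = y.attr("dim");
  std::vector<const double*> yp(k2), gp(k2);
  std::vector<double*> op(k2);
  for (int n = 0; n < N; ++n)
    for (int gr = 0; gr < groups; ++gr) {
      for (int o = 0; o < k2; ++o) {
        const size_t off = HW * ((size_t)(o + k2 * gr) + (size_t)C * n);
        yp[o] = y.begin() + off;
        gp[o] = g.begin() + off;
        op[o] = out.begin() + off;
      }
      for (size_t i = 0; i < HW; ++i) {
        double dot = 0;
        for (int o = 0; o < k2; ++o) dot += gp[o][i] * yp[o][i];
        for (int o = 0; o < k2; ++o) op[o][i] = yp[o][i] * (gp[o][i] - dot);
      }
    }
  return out;
}
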