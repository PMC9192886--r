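// Low-level numeric kernels for the nested-U generator and the simulator.
// Feature maps are column-major arrays dim (H, W, C, N); weights (kh, kw, Cin, Cout).
// Convolutions are stride-1 cross-correlations with caller-supplied zero padding
// and dilation, implemented as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H, W, C, N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, int dil, arma::mat& col) {
  // col: (kh*kw*C) x (H*W), row index r = i + kh*(j + kw*c)
  const int S = H * W;
  col.zeros(kh * kw * C, S);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * S;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dil * j - pad;
          if (iw < 0 || iw >= W) continue;
          double* dst = col.colptr(0) + r; // stride col.n_rows per column
          const double* src = xc + (size_t)iw * H;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dil * i - pad;
            if (ih < 0 || ih >= H) continue;
            dst[(size_t)(h + H * w) * col.n_rows] = src[ih];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int pad, int dil, double* gx) {
  const int S = H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * S;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dil * j - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dil * i - pad;
            if (ih < 0 || ih >= H) continue;
            gc[ih + (size_t)iw * H] += col((size_t)r, (size_t)(h + H * w));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wt, NumericVector b,
                             int pad, int dil) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  IntegerVector wd = wt.attr("dim");
  if (wd.size() != 4 || wd[2] != C) stop("weight dims do not match input channels");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int S = H * W, R = kh * kw * C;
  NumericVector y(Rcpp::no_init((size_t)S * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(wt.begin()), R, Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * S * C, H, W, C, kh, kw, pad, dil, col);
    arma::mat Y = Wm.t() * col; // Cout x S
    double* yp = y.begin() + (size_t)n * S * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bb = b[co];
      for (int s = 0; s < S; ++s) yp[(size_t)co * S + s] = Y(co, s) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wt, NumericVector gout,
                    int pad, int dil) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  IntegerVector wd = wt.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int S = H * W, R = kh * kw * C;
  NumericVector gx((size_t)S * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)R * Cout);
  gw.attr("dim") = wt.attr("dim");
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(wt.begin()), R, Cout, false, true);
  arma::mat gWm(gw.begin(), R, Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * S * C, H, W, C, kh, kw, pad, dil, col);
    arma::mat Gy(const_cast<double*>(gout.begin()) + (size_t)n * S * Cout,
                 S, Cout, false, true); // stored (H,W,Cout): S x Cout
    gWm += col * Gy;                    // R x Cout
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gy.col(co));
    arma::mat Gcol = Wm * Gy.t();       // R x S
    col2im_add(Gcol, H, W, C, kh, kw, pad, dil, gx.begin() + (size_t)n * S * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pool requires even spatial sides, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(Rcpp::no_init((size_t)Ho * Wo * C * N));
  const double* xp = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = y.begin() + cn * Ho * Wo;
    int* ic = idx.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int best = 2 * ho + H * (2 * wo);
        double bv = xc[best];
        const int cand[3] = {2 * ho + 1 + H * (2 * wo), 2 * ho + H * (2 * wo + 1),
                             2 * ho + 1 + H * (2 * wo + 1)};
        for (int t = 0; t < 3; ++t)
          if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
        yc[ho + Ho * wo] = bv;
        ic[ho + Ho * wo] = best; // offset within the (H,W) plane
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gout, int H, int W) {
  int Ho, Wo, C, N;
  get_dim4(gout, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gc = gout.begin() + cn * Ho * Wo;
    const int* ic = idx.begin() + cn * Ho * Wo;
    double* gxc = gx.begin() + cn * H * W;
    for (size_t s = 0; s < (size_t)Ho * Wo; ++s) gxc[ic[s]] += gc[s];
  }
  return gx;
}

static inline void lin_coef(int o, int Ho, int Hi, int& i0, int& i1, double& w1) {
  double src = (o + 0.5) * (double)Hi / Ho - 0.5;
  if (src < 0) src = 0;
  if (src > Hi - 1) src = Hi - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, Hi - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int o = 0; o < Ho; ++o) lin_coef(o, Ho, H, h0[o], h1[o], ah[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, Wo, W, w0[o], w1[o], aw[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = x.begin() + cn * H * W;
    double* yc = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double v00 = xc[h0[ho] + H * w0[wo]], v10 = xc[h1[ho] + H * w0[wo]];
        const double v01 = xc[h0[ho] + H * w1[wo]], v11 = xc[h1[ho] + H * w1[wo]];
        yc[ho + Ho * wo] = (1 - ah[ho]) * ((1 - aw[wo]) * v00 + aw[wo] * v01) +
                           ah[ho] * ((1 - aw[wo]) * v10 + aw[wo] * v11);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gout, int Hi, int Wi) {
  int Ho, Wo, C, N;
  get_dim4(gout, Ho, Wo, C, N);
  NumericVector gx((size_t)Hi * Wi * C * N);
  gx.attr("dim") = IntegerVector::create(Hi, Wi, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int o = 0; o < Ho; ++o) lin_coef(o, Ho, Hi, h0[o], h1[o], ah[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, Wo, Wi, w0[o], w1[o], aw[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gc = gout.begin() + cn * Ho * Wo;
    double* gxc = gx.begin() + cn * Hi * Wi;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = gc[ho + Ho * wo];
        gxc[h0[ho] + Hi * w0[wo]] += (1 - ah[ho]) * (1 - aw[wo]) * g;
        gxc[h1[ho] + Hi * w0[wo]] += ah[ho] * (1 - aw[wo]) * g;
        gxc[h0[ho] + Hi * w1[wo]] += (1 - ah[ho]) * aw[wo] * g;
        gxc[h1[ho] + Hi * w1[wo]] += ah[ho] * aw[wo] * g;
      }
    }
  }
  return gx;
}

// Sliding-window (k x k, valid) mean via summed-area tables.
// [[Rcpp::export]]
NumericVector cpp_winmean_fwd(NumericVector x, int k) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  if (k > H || k > W) stop("window larger than image side");
  const int Ho = H - k + 1, Wo = W - k + 1;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / ((double)k * k);
  std::vector<double> sat((H + 1) * (W + 1));
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = x.begin() + cn * H * W;
    for (int w = 0; w <= W; ++w) sat[(size_t)w * (H + 1)] = 0;
    for (int h = 0; h <= H; ++h) sat[h] = 0;
    for (int w = 1; w <= W; ++w)
      for (int h = 1; h <= H; ++h)
        sat[h + (size_t)w * (H + 1)] = xc[(h - 1) + H * (w - 1)] +
          sat[h - 1 + (size_t)w * (H + 1)] + sat[h + (size_t)(w - 1) * (H + 1)] -
          sat[h - 1 + (size_t)(w - 1) * (H + 1)];
    double* yc = y.begin() + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        yc[h + (size_t)w * Ho] = inv *
          (sat[h + k + (size_t)(w + k) * (H + 1)] - sat[h + (size_t)(w + k) * (H + 1)] -
           sat[h + k + (size_t)w * (H + 1)] + sat[h + (size_t)w * (H + 1)]);
  }
  return y;
}

// Adjoint of the valid-window mean: distribute each output gradient equally
// over its k x k support. Computed with a summed-area table over the gradient.
// [[Rcpp::export]]
NumericVector cpp_winmean_bwd(NumericVector gout, int H, int W, int k) {
  int Ho, Wo, C, N;
  get_dim4(gout, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / ((double)k * k);
  std::vector<double> sat((Ho + 1) * (Wo + 1));
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gc = gout.begin() + cn * Ho * Wo;
    for (int w = 0; w <= Wo; ++w) sat[(size_t)w * (Ho + 1)] = 0;
    for (int h = 0; h <= Ho; ++h) sat[h] = 0;
    for (int w = 1; w <= Wo; ++w)
      for (int h = 1; h <= Ho; ++h)
        sat[h + (size_t)w * (Ho + 1)] = gc[(h - 1) + Ho * (w - 1)] +
          sat[h - 1 + (size_t)w * (Ho + 1)] + sat[h + (size_t)(w - 1) * (Ho + 1)] -
          sat[h - 1 + (size_t)(w - 1) * (Ho + 1)];
    double* gxc = gx.begin() + cn * H * W;
    for (int w = 0; w < W; ++w) {
      const int wlo = std::max(0, w - k + 1), whi = std::min(w, Wo - 1);
      if (wlo > whi) continue;
      for (int h = 0; h < H; ++h) {
        const int hlo = std::max(0, h - k + 1), hhi = std::min(h, Ho - 1);
        if (hlo > hhi) continue;
        gxc[h + (size_t)w * H] = inv *
          (sat[hhi + 1 + (size_t)(whi + 1) * (Ho + 1)] - sat[hlo + (size_t)(whi + 1) * (Ho + 1)] -
           sat[hhi + 1 + (size_t)wlo * (Ho + 1)] + sat[hlo + (size_t)wlo * (Ho + 1)]);
      }
    }
  }
  return gx;
}

// Separable Gaussian blur of a 3-D volume (zero boundary, normalized kernel).
// sigma is in voxels, one value per axis; an axis with sigma <= 0 is skipped.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector x, NumericVector sigma) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-D volume");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  const int dims[3] = {n0, n1, n2};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += ker[i + r]; }
    for (double& v : ker) v /= tot;
    const int len = dims[ax];
    // strides for (n0, n1, n2) column-major
    const size_t str[3] = {1, (size_t)n0, (size_t)n0 * n1};
    const size_t stride = str[ax];
    const size_t nline = (size_t)n0 * n1 * n2 / len;
    // iterate all lines along axis ax
    for (size_t line = 0; line < nline; ++line) {
      // decompose line index over remaining axes
      size_t rem = line, base = 0;
      for (int axo = 0; axo < 3; ++axo) {
        if (axo == ax) continue;
        const size_t idx = rem % dims[axo];
        rem /= dims[axo];
        base += idx * str[axo];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        const int jlo = std::max(0, i - r), jhi = std::min(len - 1, i + r);
        for (int j = jlo; j <= jhi; ++j) acc += ker[j - i + r] * a[base + (size_t)j * stride];
        b[base + (size_t)i * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// World-coordinate resampling of a 3-D volume onto a target grid.
// Voxel i (0-based) has its center at origin + i * spacing along each axis.
// Border policy: clamp to the nearest edge voxel.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector src, NumericVector src_spacing,
                             NumericVector src_origin, IntegerVector dst_shape,
                             NumericVector dst_spacing, NumericVector dst_origin,
                             bool nearest) {
  IntegerVector d = src.attr("dim");
  if (d.size() != 3) stop("expected a 3-D volume");
  const int s0 = d[0], s1 = d[1], s2 = d[2];
  const int t0 = dst_shape[0], t1 = dst_shape[1], t2 = dst_shape[2];
  NumericVector out(Rcpp::no_init((size_t)t0 * t1 * t2));
  out.attr("dim") = IntegerVector::create(t0, t1, t2);
  const double* sp = src.begin();
  auto clampi = [](double v, int hi) {
    if (v < 0) return 0.0;
    if (v > hi) return (double)hi;
    return v;
  };
  size_t o = 0;
  for (int k = 0; k < t2; ++k) {
    const double z = (dst_origin[2] + k * dst_spacing[2] - src_origin[2]) / src_spacing[2];
    const double zc = clampi(z, s2 - 1);
    for (int j = 0; j < t1; ++j) {
      const double y = (dst_origin[1] + j * dst_spacing[1] - src_origin[1]) / src_spacing[1];
      const double yc = clampi(y, s1 - 1);
      for (int i = 0; i < t0; ++i, ++o) {
        const double x = (dst_origin[0] + i * dst_spacing[0] - src_origin[0]) / src_spacing[0];
        const double xc = clampi(x, s0 - 1);
        if (nearest) {
          const int i0 = (int)std::lround(xc), j0 = (int)std::lround(yc), k0 = (int)std::lround(zc);
          out[o] = sp[i0 + (size_t)s0 * (j0 + (size_t)s1 * k0)];
        } else {
          const int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc), z0 = (int)std::floor(zc);
          const int x1 = std::min(x0 + 1, s0 - 1), y1 = std::min(y0 + 1, s1 - 1),
                    z1 = std::min(z0 + 1, s2 - 1);
          const double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          auto at = [&](int a, int b, int c) {
            return sp[a + (size_t)s0 * (b + (size_t)s1 * c)];
          };
          const double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
          const double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
          const double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
          const double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
          out[o] = ((c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz);
        }
      }
    }
  }
  return out;
}

// Channel normalization over the (H, W, N) axes with learnable gain/shift.
// Returns y plus the per-channel mean and inverse standard deviation needed
// by the backward pass.
// [[Rcpp::export]]
List cpp_norm_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const size_t S = (size_t)H * W;
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  NumericVector mu(C), inv(C);
  const double m = (double)S * N;
  for (int c = 0; c < C; ++c) {
    double acc = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + S * (c + (size_t)C * n);
      for (size_t s = 0; s < S; ++s) acc += xc[s];
    }
    const double mc = acc / m;
    double v = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + S * (c + (size_t)C * n);
      for (size_t s = 0; s < S; ++s) { const double d = xc[s] - mc; v += d * d; }
    }
    const double ic = 1.0 / std::sqrt(v / m + eps);
    mu[c] = mc; inv[c] = ic;
    const double a = gamma[c] * ic, b = beta[c] - gamma[c] * ic * mc;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + S * (c + (size_t)C * n);
      double* yc = y.begin() + S * (c + (size_t)C * n);
      for (size_t s = 0; s < S; ++s) yc[s] = a * xc[s] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_norm_bwd(NumericVector x, NumericVector gamma, NumericVector mu,
                  NumericVector inv, NumericVector gout) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  const size_t S = (size_t)H * W;
  const double m = (double)S * N;
  NumericVector gx(Rcpp::no_init(x.size()));
  gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + S * (c + (size_t)C * n);
      const double* gc = gout.begin() + S * (c + (size_t)C * n);
      for (size_t s = 0; s < S; ++s) {
        sg += gc[s];
        sgx += gc[s] * (xc[s] - mu[c]) * inv[c];
      }
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    const double mg = sg / m, mgx = sgx / m;
    const double a = gamma[c] * inv[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + S * (c + (size_t)C * n);
      const double* gc = gout.begin() + S * (c + (size_t)C * n);
      double* oc = gx.begin() + S * (c + (size_t)C * n);
      for (size_t s = 0; s < S; ++s) {
        const double xh = (xc[s] - mu[c]) * inv[c];
        oc[s] = a * (gc[s] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
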