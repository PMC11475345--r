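// Low-level kernels for the conv-net graph engine.
// Tensor layout everywhere: R array with dim = (H, W, C, N), column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// im2col for one sample/group: returns (cin_g*kh*kw) x (Hout*Wout)
// row index r = ci*kh*kw + i*kw + j ; column index = ho + Hout*wo
static void im2col(const double* img, int H, int W, int cin_g, int c0,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Hout, int Wout, arma::mat& col) {
  for (int ci = 0; ci < cin_g; ++ci) {
    const double* plane = img + (size_t)(c0 + ci) * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        int r = ci * kh * kw + i * kw + j;
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * sw - pw + j * dw;
          double* dst = col.memptr() + (size_t)r * Hout * Wout + (size_t)wo * Hout;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Hout, 0.0);
            continue;
          }
          const double* src = plane + (size_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * sh - ph + i * dh;
            dst[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, double* img, int H, int W, int cin_g,
                   int c0, int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Hout, int Wout) {
  for (int ci = 0; ci < cin_g; ++ci) {
    double* plane = img + (size_t)(c0 + ci) * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        int r = ci * kh * kw + i * kw + j;
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * sw - pw + j * dw;
          if (wi < 0 || wi >= W) continue;
          const double* src = col.memptr() + (size_t)r * Hout * Wout + (size_t)wo * Hout;
          double* dstp = plane + (size_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * sh - ph + i * dh;
            if (hi >= 0 && hi < H) dstp[hi] += src[ho];
          }
        }
      }
    }
  }
}

// weight layout from R: dim (kh, kw, cin_g, cout) column-major.
// We build per-group weight matrix Wg: (cout_g) x (cin_g*kh*kw) with the
// same row index convention as im2col.
static arma::mat weight_mat(const NumericVector& wt, int kh, int kw, int cin_g,
                            int cout_g, int co0) {
  arma::mat Wm(cout_g, cin_g * kh * kw);
  for (int co = 0; co < cout_g; ++co)
    for (int ci = 0; ci < cin_g; ++ci)
      for (int i = 0; i < kh; ++i)
        for (int j = 0; j < kw; ++j) {
          size_t widx = (size_t)i + kh * ((size_t)j + kw * ((size_t)ci + (size_t)cin_g * (co0 + co)));
          Wm(co, ci * kh * kw + i * kw + j) = wt[widx];
        }
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim, NumericVector wt,
                        Nullable<NumericVector> bias, int kh, int kw, int sh, int sw,
                        int ph, int pw, int dh, int dw, int groups, int cout) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Hout = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  int Wout = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  int cin_g = C / groups, cout_g = cout / groups;
  NumericVector out = make4(Hout, Wout, cout, N);
  size_t HWo = (size_t)Hout * Wout;
  arma::mat col(HWo, cin_g * kh * kw);
  std::vector<arma::mat> Wg(groups);
  for (int g = 0; g < groups; ++g)
    Wg[g] = weight_mat(wt, kh, kw, cin_g, cout_g, g * cout_g);
  for (int n = 0; n < N; ++n) {
    const double* img = x.begin() + (size_t)n * H * W * C;
    double* outp = out.begin() + (size_t)n * HWo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(img, H, W, cin_g, g * cin_g, kh, kw, sh, sw, ph, pw, dh, dw, Hout, Wout, col);
      arma::mat res = col * Wg[g].t();  // (Hout*Wout) x cout_g
      for (int co = 0; co < cout_g; ++co) {
        double b = bias.isNotNull() ? NumericVector(bias)[g * cout_g + co] : 0.0;
        double* dst = outp + (size_t)(g * cout_g + co) * HWo;
        const double* srcr = res.colptr(co);
        for (size_t q = 0; q < HWo; ++q) dst[q] = srcr[q] + b;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, IntegerVector xdim, NumericVector wt, NumericVector gout,
               bool has_bias, int kh, int kw, int sh, int sw, int ph, int pw,
               int dh, int dw, int groups, int cout, bool need_dx) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Hout = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  int Wout = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  int cin_g = C / groups, cout_g = cout / groups;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dwt(wt.size());
  NumericVector db(has_bias ? cout : 1);
  size_t HWo = (size_t)Hout * Wout;
  arma::mat col(HWo, cin_g * kh * kw);
  std::vector<arma::mat> Wg(groups), dWg(groups);
  for (int g = 0; g < groups; ++g) {
    Wg[g] = weight_mat(wt, kh, kw, cin_g, cout_g, g * cout_g);
    dWg[g] = arma::zeros(cout_g, cin_g * kh * kw);
  }
  for (int n = 0; n < N; ++n) {
    const double* img = x.begin() + (size_t)n * H * W * C;
    const double* gp = gout.begin() + (size_t)n * HWo * cout;
    double* dxp = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      arma::mat G(HWo, cout_g);
      for (int co = 0; co < cout_g; ++co) {
        const double* src = gp + (size_t)(g * cout_g + co) * HWo;
        std::copy(src, src + HWo, G.colptr(co));
        if (has_bias) db[g * cout_g + co] += arma::accu(G.col(co));
      }
      im2col(img, H, W, cin_g, g * cin_g, kh, kw, sh, sw, ph, pw, dh, dw, Hout, Wout, col);
      dWg[g] += G.t() * col;
      if (need_dx) {
        arma::mat dcol = G * Wg[g];  // (Hout*Wout) x (cin_g*kh*kw)
        col2im(dcol, dxp, H, W, cin_g, g * cin_g, kh, kw, sh, sw, ph, pw, dh, dw, Hout, Wout);
      }
    }
  }
  // scatter dWg back to the R weight layout
  for (int g = 0; g < groups; ++g)
    for (int co = 0; co < cout_g; ++co)
      for (int ci = 0; ci < cin_g; ++ci)
        for (int i = 0; i < kh; ++i)
          for (int j = 0; j < kw; ++j) {
            size_t widx = (size_t)i + kh * ((size_t)j + kw * ((size_t)ci + (size_t)cin_g * (g * cout_g + co)));
            dwt[widx] = dWg[g](co, ci * kh * kw + i * kw + j);
          }
  return List::create(_["dx"] = dx, _["dw"] = dwt, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, IntegerVector xdim, int k, int s, int p) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Hout = (H + 2 * p - k) / s + 1;
  int Wout = (W + 2 * p - k) / s + 1;
  NumericVector out = make4(Hout, Wout, C, N);
  IntegerVector idx(out.size());  // linear index into x of the max element
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      size_t obase = ((size_t)n * C + c) * Hout * Wout;
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i;
              if (hi < 0 || hi >= H) continue;
              double v = plane[hi + (size_t)wi * H];
              if (v > best) { best = v; bi = hi + wi * H; }
            }
          }
          out[obase + ho + (size_t)wo * Hout] = best;
          idx[obase + ho + (size_t)wo * Hout] = bi;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector gout, IntegerVector idx, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx = make4(H, W, C, N);
  int HWo = gout.size() / (C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t obase = ((size_t)n * C + c) * HWo;
      double* dplane = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int q = 0; q < HWo; ++q) {
        int bi = idx[obase + q];
        if (bi >= 0) dplane[bi] += gout[obase + q];
      }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fw(NumericVector x, IntegerVector xdim, int k, int s, int p) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Hout = (H + 2 * p - k) / s + 1;
  int Wout = (W + 2 * p - k) / s + 1;
  NumericVector out = make4(Hout, Wout, C, N);
  double inv = 1.0 / (k * k);  // count_include_pad
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      size_t obase = ((size_t)n * C + c) * Hout * Wout;
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double acc = 0.0;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i;
              if (hi < 0 || hi >= H) continue;
              acc += plane[hi + (size_t)wi * H];
            }
          }
          out[obase + ho + (size_t)wo * Hout] = acc * inv;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_bw(NumericVector gout, IntegerVector xdim, int k, int s, int p) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Hout = (H + 2 * p - k) / s + 1;
  int Wout = (W + 2 * p - k) / s + 1;
  NumericVector dx = make4(H, W, C, N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dplane = dx.begin() + ((size_t)n * C + c) * H * W;
      size_t obase = ((size_t)n * C + c) * Hout * Wout;
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double g = gout[obase + ho + (size_t)wo * Hout] * inv;
          for (int j = 0; j < k; ++j) {
            int wi = wo * s - p + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * s - p + i;
              if (hi >= 0 && hi < H) dplane[hi + (size_t)wi * H] += g;
            }
          }
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2x_fw(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector out = make4(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      double* op = out.begin() + ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < 2 * W; ++w)
        for (int h = 0; h < 2 * H; ++h)
          op[h + (size_t)w * 2 * H] = plane[(h / 2) + (size_t)(w / 2) * H];
    }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2x_bw(NumericVector gout, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx = make4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dplane = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* gp = gout.begin() + ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < 2 * W; ++w)
        for (int h = 0; h < 2 * H; ++h)
          dplane[(h / 2) + (size_t)(w / 2) * H] += gp[h + (size_t)w * 2 * H];
    }
  return dx;
}
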