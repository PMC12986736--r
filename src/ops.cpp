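// Low-level tensor primitives for the U-Net++ segmenter.
//
// Activations are dense column-major double arrays with dim [H, W, C, B]
// (height, width, channels, batch). 3x3 convolutions are 'same' (zero
// padded, stride 1) and run as nine whole-batch GEMMs over shifted views
// of a zero-padded channel-major buffer, so BLAS sees tall well-shaped
// matrices and no im2col matrix is ever materialized. Conv weights are
// [K*K*Cin, Cout] with rows ordered channel-fastest within each kernel
// offset (r = c + Cin * ((dh+1) + 3*(dw+1))).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d [H,W,C,B] array");
  H = dm[0]; W = dm[1]; C = dm[2]; B = dm[3];
}

static NumericVector make4d(int H, int W, int C, int B) {
  NumericVector y((R_xlen_t)H * W * C * B);
  y.attr("dim") = IntegerVector::create(H, W, C, B);
  return y;
}

// copy [H,W,C,B] into the padded channel-major layout: plane p of image b
// for channel c lives at base[c*(P*B) + b*P], P = (H+2)*(W+2), with a
// one-pixel zero border per plane.
static void pad_batch(const double* x, int H, int W, int C, int B,
                      double* base) {
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = (size_t)Hp * Wp;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double* src = x + ((size_t)b * C + c) * H * W;
      double* dst = base + ((size_t)c * B + b) * P;
      for (int w = 0; w < W; ++w)
        std::memcpy(dst + (size_t)(w + 1) * Hp + 1, src + (size_t)w * H,
                    sizeof(double) * H);
    }
  }
}

// total channel count of a list of [H,W,Ci,B] parts sharing H,W,B
static int parts_dims(const List& xs, int& H, int& W, int& B,
                      std::vector<int>& cs) {
  int C = 0;
  cs.resize(xs.size());
  for (int k = 0; k < xs.size(); ++k) {
    NumericVector x = xs[k];
    int h, w, c, b; get_dims(x, h, w, c, b);
    if (k == 0) { H = h; W = w; B = b; }
    else if (h != H || w != W || b != B) stop("input parts: incompatible dims");
    cs[k] = c; C += c;
  }
  return C;
}

// pad all parts into one channel-major padded buffer (channels stacked in
// part order)
static void pad_parts(const List& xs, const std::vector<int>& cs,
                      int H, int W, int B, double* base) {
  const size_t P = (size_t)(H + 2) * (W + 2);
  size_t coff = 0;
  for (int k = 0; k < xs.size(); ++k) {
    NumericVector x = xs[k];
    pad_batch(x.begin(), H, W, cs[k], B, base + coff * P * B);
    coff += cs[k];
  }
}

// 'same' convolution of the channel-concatenation of the parts in `xs`,
// with optional fused ReLU
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(List xs, NumericMatrix w, NumericVector b,
                           bool relu = false) {
  int H, W, B;
  std::vector<int> cs;
  const int C = parts_dims(xs, H, W, B, cs);
  if (w.nrow() % C != 0) stop("weight rows incompatible with input channels");
  const int KK = w.nrow() / C;
  if (KK != 1 && KK != 9) stop("kernel must be 1x1 or 3x3");
  const int Cout = w.ncol();
  NumericVector y = make4d(H, W, Cout, B);
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), Cout,
                     false, true);
  if (KK == 1) {
    if (xs.size() != 1) stop("1x1 conv expects a single input part");
    NumericVector x = xs[0];
    for (int bi = 0; bi < B; ++bi) {
      const arma::mat X(const_cast<double*>(x.begin()) +
                        (size_t)bi * H * W * C, (size_t)H * W, C, false, true);
      arma::mat Y(y.begin() + (size_t)bi * H * W * Cout, (size_t)H * W, Cout,
                  false, true);
      Y = X * Wm;
      for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
    }
    if (relu) { double* p = y.begin();
      for (R_xlen_t i = 0; i < y.size(); ++i) if (p[i] < 0) p[i] = 0; }
    return y;
  }
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = (size_t)Hp * Wp, M = P * B, G = Hp + 2;
  std::vector<double> xp(M * C + 2 * G, 0.0);
  double* base = xp.data() + G;
  pad_parts(xs, cs, H, W, B, base);
  arma::mat Y(M, Cout);
  int k = 0;
  for (int dw = -1; dw <= 1; ++dw) {
    for (int dh = -1; dh <= 1; ++dh, ++k) {
      const long shift = dh + (long)dw * Hp;
      const arma::mat A(base + shift, M, C, false, true);
      const arma::mat Wk = Wm.rows((size_t)k * C, (size_t)k * C + C - 1);
      if (k == 0) Y = A * Wk; else Y += A * Wk;
    }
  }
  double* py = y.begin();
  for (int bi = 0; bi < B; ++bi) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + (size_t)bi * P;
      double* dst = py + ((size_t)bi * Cout + co) * H * W;
      const double bb = b[co];
      for (int wq = 0; wq < W; ++wq) {
        const double* s = src + (size_t)(wq + 1) * Hp + 1;
        double* d = dst + (size_t)wq * H;
        if (relu) for (int h = 0; h < H; ++h) {
          const double v = s[h] + bb; d[h] = v > 0 ? v : 0;
        } else for (int h = 0; h < H; ++h) d[h] = s[h] + bb;
      }
    }
  }
  return y;
}

// backward of cpp_conv_fwd; dx is returned split into the same parts as xs
// [[Rcpp::export]]
List cpp_conv_bwd(List xs, NumericMatrix w, NumericVector dy) {
  int H, W, B;
  std::vector<int> cs;
  const int C = parts_dims(xs, H, W, B, cs);
  const int KK = w.nrow() / C;
  const int Cout = w.ncol();
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), Cout,
                     false, true);
  arma::mat dWm(dw.begin(), w.nrow(), Cout, false, true);
  List dxs(xs.size());
  for (int k = 0; k < xs.size(); ++k) dxs[k] = make4d(H, W, cs[k], B);
  if (KK == 1) {
    NumericVector x = xs[0];
    NumericVector dx = dxs[0];
    for (int bi = 0; bi < B; ++bi) {
      const arma::mat X(const_cast<double*>(x.begin()) +
                        (size_t)bi * H * W * C, (size_t)H * W, C, false, true);
      const arma::mat dY(const_cast<double*>(dy.begin()) +
                         (size_t)bi * H * W * Cout, (size_t)H * W, Cout,
                         false, true);
      dWm += X.t() * dY;
      arma::mat dX(dx.begin() + (size_t)bi * H * W * C, (size_t)H * W, C,
                   false, true);
      dX = dY * Wm.t();
      for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    }
    return List::create(_["dx"] = dxs, _["dw"] = dw, _["db"] = db);
  }
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = (size_t)Hp * Wp, M = P * B, G = Hp + 2;
  std::vector<double> xp(M * C + 2 * G, 0.0);
  double* base = xp.data() + G;
  pad_parts(xs, cs, H, W, B, base);
  // padded gradient of the output (zeros at borders and guards)
  std::vector<double> dyp(M * Cout, 0.0);
  pad_batch(dy.begin(), H, W, Cout, B, dyp.data());
  arma::mat dYm(dyp.data(), M, Cout, false, true);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dYm.col(co));
  std::vector<double> dxp(M * C + 2 * G, 0.0);
  double* dxbase = dxp.data() + G;
  int k = 0;
  for (int dw_ = -1; dw_ <= 1; ++dw_) {
    for (int dh = -1; dh <= 1; ++dh, ++k) {
      const long shift = dh + (long)dw_ * Hp;
      const arma::mat A(base + shift, M, C, false, true);
      dWm.rows((size_t)k * C, (size_t)k * C + C - 1) = A.t() * dYm;
      const arma::mat Wk = Wm.rows((size_t)k * C, (size_t)k * C + C - 1);
      arma::mat V(dxbase + shift, M, C, false, true);
      V += dYm * Wk.t();
    }
  }
  // split the interior of dxp back into the parts
  size_t coff = 0;
  for (int kpart = 0; kpart < xs.size(); ++kpart) {
    NumericVector dx = dxs[kpart];
    double* pdx = dx.begin();
    for (int c = 0; c < cs[kpart]; ++c) {
      for (int bi = 0; bi < B; ++bi) {
        const double* src = dxbase + ((coff + c) * B + bi) * P;
        double* dst = pdx + ((size_t)bi * cs[kpart] + c) * H * W;
        for (int wq = 0; wq < W; ++wq)
          std::memcpy(dst + (size_t)wq * H, src + (size_t)(wq + 1) * Hp + 1,
                      sizeof(double) * H);
      }
    }
    coff += cs[kpart];
  }
  return List::create(_["dx"] = dxs, _["dw"] = dw, _["db"] = db);
}

// dy * (y > 0), single pass
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* pd = dy.begin();
  const double* py = y.begin();
  double* po = out.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = py[i] > 0 ? pd[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  int H, W, C, B; get_dims(x, H, W, C, B);
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B);
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  R_xlen_t o = 0;
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const size_t basei = ((size_t)bi * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          const size_t i00 = basei + (size_t)(2 * wo) * H + 2 * ho;
          size_t best = i00;
          double v = px[i00];
          const size_t cand[3] = { i00 + 1, i00 + (size_t)H,
                                   i00 + (size_t)H + 1 };
          for (int kk = 0; kk < 3; ++kk)
            if (px[cand[kk]] > v) { v = px[cand[kk]]; best = cand[kk]; }
          py[o] = v;
          pi[o] = (int)best;  // linear index into x; sizes stay below 2^31
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  NumericVector dx = make4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  const int* pi = idx.begin();
  const double* pd = dy.begin();
  double* px = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) px[pi[i]] += pd[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x) {
  int H, W, C, B; get_dims(x, H, W, C, B);
  NumericVector y = make4d(2 * H, 2 * W, C, B);
  const double* px = x.begin();
  double* py = y.begin();
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const double* s = px + ((size_t)bi * C + c) * H * W;
      double* d = py + ((size_t)bi * C + c) * 4 * H * W;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const double v = s[(size_t)w * H + h];
          const size_t o = (size_t)(2 * w) * 2 * H + 2 * h;
          d[o] = v; d[o + 1] = v;
          d[o + 2 * H] = v; d[o + 2 * H + 1] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy) {
  int H2, W2, C, B; get_dims(dy, H2, W2, C, B);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx = make4d(H, W, C, B);
  const double* pd = dy.begin();
  double* px = dx.begin();
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const double* s = pd + ((size_t)bi * C + c) * 4 * H * W;
      double* d = px + ((size_t)bi * C + c) * H * W;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const size_t o = (size_t)(2 * w) * 2 * H + 2 * h;
          d[(size_t)w * H + h] = s[o] + s[o + 1] + s[o + 2 * H] +
            s[o + 2 * H + 1];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_concat_ch(List xs) {
  const int n = xs.size();
  int H = 0, W = 0, B = 0, Ct = 0;
  std::vector<int> cs(n);
  for (int k = 0; k < n; ++k) {
    NumericVector x = xs[k];
    int h, w, c, b; get_dims(x, h, w, c, b);
    if (k == 0) { H = h; W = w; B = b; }
    else if (h != H || w != W || b != B) stop("concat: incompatible dims");
    cs[k] = c; Ct += c;
  }
  NumericVector y = make4d(H, W, Ct, B);
  double* py = y.begin();
  for (int bi = 0; bi < B; ++bi) {
    size_t off = (size_t)bi * H * W * Ct;
    for (int k = 0; k < n; ++k) {
      NumericVector x = xs[k];
      const size_t blk = (size_t)H * W * cs[k];
      std::memcpy(py + off, x.begin() + (size_t)bi * blk,
                  sizeof(double) * blk);
      off += blk;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_split_ch(NumericVector dy, IntegerVector sizes) {
  int H, W, Ct, B; get_dims(dy, H, W, Ct, B);
  const int n = sizes.size();
  List out(n);
  std::vector<double*> ptrs(n);
  for (int k = 0; k < n; ++k) {
    NumericVector d = make4d(H, W, sizes[k], B);
    ptrs[k] = d.begin();
    out[k] = d;
  }
  const double* pd = dy.begin();
  for (int bi = 0; bi < B; ++bi) {
    size_t off = (size_t)bi * H * W * Ct;
    for (int k = 0; k < n; ++k) {
      const size_t blk = (size_t)H * W * sizes[k];
      std::memcpy(ptrs[k] + (size_t)bi * blk, pd + off,
                  sizeof(double) * blk);
      off += blk;
    }
  }
  return out;
}

// Batch normalization over (H,W,B) per channel, with optional fused ReLU.
// Returns the activation plus the batch mean and (biased) variance needed
// for backprop and for the running inference statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps, bool relu = true) {
  int H, W, C, B; get_dims(x, H, W, C, B);
  const size_t HW = (size_t)H * W;
  const R_xlen_t n = x.size();
  NumericVector y(n);
  y.attr("dim") = x.attr("dim");
  NumericVector mean_out(C), var_out(C);
  const double* px = x.begin();
  double* py = y.begin();
  const double N = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = px + ((size_t)b * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double mu = s / N;
    double v = s2 / N - mu * mu;
    if (v < 0) v = 0;
    mean_out[c] = mu; var_out[c] = v;
    const double inv = gamma[c] / std::sqrt(v + eps);
    const double shift = beta[c] - mu * inv;
    for (int b = 0; b < B; ++b) {
      const double* p = px + ((size_t)b * C + c) * HW;
      double* q = py + ((size_t)b * C + c) * HW;
      if (relu) for (size_t i = 0; i < HW; ++i) {
        const double t = p[i] * inv + shift; q[i] = t > 0 ? t : 0;
      } else for (size_t i = 0; i < HW; ++i) q[i] = p[i] * inv + shift;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean_out, _["var"] = var_out);
}

// normalization with fixed (running) statistics, for inference
// [[Rcpp::export]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean_in,
                          NumericVector var_in, double eps,
                          bool relu = true) {
  int H, W, C, B; get_dims(x, H, W, C, B);
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = gamma[c] / std::sqrt(var_in[c] + eps);
    const double shift = beta[c] - mean_in[c] * inv;
    for (int b = 0; b < B; ++b) {
      const double* p = px + ((size_t)b * C + c) * HW;
      double* q = py + ((size_t)b * C + c) * HW;
      if (relu) for (size_t i = 0; i < HW; ++i) {
        const double t = p[i] * inv + shift; q[i] = t > 0 ? t : 0;
      } else for (size_t i = 0; i < HW; ++i) q[i] = p[i] * inv + shift;
    }
  }
  return y;
}

// backward of cpp_bn_fwd; y is the forward output (for the ReLU mask)
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean_in,
                NumericVector var_in, double eps, NumericVector dy,
                NumericVector y, bool relu = true) {
  int H, W, C, B; get_dims(x, H, W, C, B);
  const size_t HW = (size_t)H * W;
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const double* px = x.begin();
  const double* pd = dy.begin();
  const double* pyv = y.begin();
  double* pdx = dx.begin();
  const double N = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    const double mu = mean_in[c];
    const double istd = 1.0 / std::sqrt(var_in[c] + eps);
    double s0 = 0, s1 = 0;
    for (int b = 0; b < B; ++b) {
      const size_t off = ((size_t)b * C + c) * HW;
      const double* p = px + off;
      const double* d = pd + off;
      const double* yy = pyv + off;
      for (size_t i = 0; i < HW; ++i) {
        const double g = (!relu || yy[i] > 0) ? d[i] : 0.0;
        s0 += g;
        s1 += g * (p[i] - mu) * istd;
      }
    }
    dbeta[c] = s0;
    dgamma[c] = s1;
    const double k = gamma[c] * istd / N;
    for (int b = 0; b < B; ++b) {
      const size_t off = ((size_t)b * C + c) * HW;
      const double* p = px + off;
      const double* d = pd + off;
      const double* yy = pyv + off;
      double* o = pdx + off;
      for (size_t i = 0; i < HW; ++i) {
        const double g = (!relu || yy[i] > 0) ? d[i] : 0.0;
        const double xh = (p[i] - mu) * istd;
        o[i] = k * (N * g - s0 - xh * s1);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
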