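// Low-level numeric kernels for the CNN layers.
//
// All image tensors use the R array layout H x W x C x N (column-major,
// H fastest), matching how the R side stores batches. Convolutions are
// stride-1 with "same" zero padding derived from the kernel size (even
// kernels pad one extra pixel on the bottom/right).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4(int d1, int d2, int d3, int d4) {
  NumericVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Unpack one sample into an im2col matrix: rows index (kh, kw, cin),
// columns index output pixels (h fastest), zeros outside the image.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int ph0, int pw0, arma::mat& cols) {
  const int HW = H * W;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + j - pw0;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (size_t)wi * H;
          double* dst = cols.colptr(0) + r; // cols is (R x HW); manual stride below
          const int h0 = std::max(0, ph0 - i);
          const int h1 = std::min(H, H + ph0 - i);
          for (int ho = h0; ho < h1; ++ho) {
            const int hi = ho + i - ph0;
            // column index = ho + H*wo
            dst[(size_t)(ho + (size_t)H * wo) * cols.n_rows] = src[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back onto the input image.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int ph0, int pw0, double* gx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * HW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + j - pw0;
          if (wi < 0 || wi >= W) continue;
          double* dstc = gc + (size_t)wi * H;
          const int h0 = std::max(0, ph0 - i);
          const int h1 = std::min(H, H + ph0 - i);
          for (int ho = h0; ho < h1; ++ho) {
            const int hi = ho + i - ph0;
            dstc[hi] += cols.at(r, (size_t)ho + (size_t)H * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, cin, cout)");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("input channels do not match kernel");
  const int ph0 = (kh - 1) / 2, pw0 = (kw - 1) / 2;
  const int HW = H * W, R = kh * kw * C;

  NumericVector out = make4(H, W, cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), R, cout, false, true);
  arma::mat cols(R, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, ph0, pw0, cols);
    arma::mat o(out.begin() + (size_t)n * HW * cout, HW, cout, false, true);
    o = cols.t() * wm;
    for (int co = 0; co < cout; ++co) o.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector gout) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  const int ph0 = (kh - 1) / 2, pw0 = (kw - 1) / 2;
  const int HW = H * W, R = kh * kw * C;

  NumericVector gx = make4(H, W, C, N);
  NumericVector gw = make4(kh, kw, C, cout);
  NumericVector gb(cout);
  arma::mat wm(const_cast<double*>(w.begin()), R, cout, false, true);
  arma::mat gwm(gw.begin(), R, cout, false, true);
  arma::vec gbv(gb.begin(), cout, false, true);
  arma::mat cols(R, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, ph0, pw0, cols);
    arma::mat g(const_cast<double*>(gout.begin()) + (size_t)n * HW * cout,
                HW, cout, false, true);
    gwm += cols * g;
    gbv += arma::sum(g, 0).t();
    arma::mat gcols = wm * g.t(); // R x HW
    col2im(gcols, H, W, C, kh, kw, ph0, pw0, gx.begin() + (size_t)n * HW * C);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % k != 0 || W % k != 0) stop("spatial size not divisible by pool window");
  const int Ho = H / k, Wo = W / k;
  NumericVector out = make4(Ho, Wo, C, N);
  IntegerVector idx(out.size()); // 1-based linear index into x of each max
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dw = 0; dw < k; ++dw) {
            const size_t coloff = base + (size_t)(wo * k + dw) * H;
            for (int dh = 0; dh < k; ++dh) {
              const size_t ii = coloff + ho * k + dh;
              if (x[ii] > best) { best = x[ii]; besti = ii; }
            }
          }
          out[o] = best;
          idx[o] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector gout, IntegerVector xdim) {
  NumericVector gx = make4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}
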