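#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: image batches are R arrays of dim (H, W, C, N), column
// major. im2col rows are ordered h-fastest, then w, then n, so the matrix
// product (rows x K*K*C) %*% (K*K*C x F) reshapes directly to (H, W, N, F).
// Stride 1, 'same' zero padding (pad = K / 2).

// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector x, int H, int W, int C, int N, int K) {
  const int pad = K / 2;
  NumericMatrix out((R_xlen_t)H * W * N, (R_xlen_t)K * K * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int j = kh + K * kw + K * K * c;
        double* col = &out(0, j);
        for (int n = 0; n < N; ++n) {
          const double* img = px + ((R_xlen_t)n * C + c) * H * W;
          R_xlen_t row = (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int wi = w + kw - pad;
            if (wi < 0 || wi >= W) { row += H; continue; }
            const double* src = img + (R_xlen_t)wi * H;
            for (int h = 0; h < H; ++h, ++row) {
              const int hi = h + kh - pad;
              if (hi >= 0 && hi < H) col[row] = src[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col_batch: scatter-add column gradients back onto the image
// [[Rcpp::export]]
NumericVector col2im_batch(NumericMatrix cols, int H, int W, int C, int N, int K) {
  const int pad = K / 2;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int j = kh + K * kw + K * K * c;
        const double* col = &cols(0, j);
        for (int n = 0; n < N; ++n) {
          double* img = px + ((R_xlen_t)n * C + c) * H * W;
          R_xlen_t row = (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int wi = w + kw - pad;
            if (wi < 0 || wi >= W) { row += H; continue; }
            double* dst = img + (R_xlen_t)wi * H;
            for (int h = 0; h < H; ++h, ++row) {
              const int hi = h + kh - pad;
              if (hi >= 0 && hi < H) dst[hi] += col[row];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2; also returns 1-based argmax indices into the
// input vector so the backward pass is a pure scatter
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* px = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          R_xlen_t best = base + (R_xlen_t)(2 * w) * H + 2 * h;
          double bv = px[best];
          const R_xlen_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k) {
            if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
          }
          out[o] = bv;
          idx[o] = (int)(best + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dout, IntegerVector idx, R_xlen_t len_in) {
  NumericVector dx(len_in);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i] - 1] += dout[i];
  return dx;
}

// rigid augmentation warp: rotate by angle (degrees, about the image centre),
// translate by (dr, dc) pixels, scale intensities by gain; bilinear sampling
// with zero background. Inverse mapping, so no holes.
// [[Rcpp::export]]
NumericMatrix warp_rigid(NumericMatrix img, double angle_deg, double dr,
                         double dc, double gain) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const double yr = (h - dr) - cr, xc = (w - dc) - cc;
      const double sy = ct * yr + st * xc + cr;
      const double sx = -st * yr + ct * xc + cc;
      const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      const double fy = sy - y0, fx = sx - x0;
      double acc = 0.0;
      for (int b = 0; b < 2; ++b) {
        for (int a = 0; a < 2; ++a) {
          const int yy = y0 + a, xx = x0 + b;
          if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
            const double wgt = (a ? fy : 1 - fy) * (b ? fx : 1 - fx);
            acc += wgt * img(yy, xx);
          }
        }
      }
      out(h, w) = gain * acc;
    }
  }
  return out;
}
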