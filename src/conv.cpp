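// Same-padding 2D convolution primitives for the decoder network.
//
// Feature maps are (H*W*N) x C column-major matrices whose rows run over
// image rows, then columns, then batch samples. Convolution is evaluated as
// im2col followed by one BLAS matrix product; the backward pass reuses the
// same patch layout. Only these inner loops live in C++ — the autodiff tape
// and network logic stay in R.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill P (zero-initialized, HWN x k*k*C) with same-padding patches of x.
// Offset block `off` (kernel row di fastest, then kernel column dj) holds
// the input shifted by (di - p, dj - p); out-of-frame positions stay zero.
static void im2col_fill(const arma::mat& x, arma::mat& P,
                        const int H, const int W, const int N, const int k) {
  const int C = x.n_cols, p = (k - 1) / 2, HW = H * W;
  int off = 0;
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di, ++off) {
      const int si0 = di - p, sj0 = dj - p;
      const int i_lo = std::max(0, -si0), i_hi = std::min(H, H - si0);
      if (i_hi <= i_lo) continue;
      for (int c = 0; c < C; ++c) {
        double* dst0 = P.colptr(off * C + c);
        const double* src0 = x.colptr(c);
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int sj = j + sj0;
            if (sj < 0 || sj >= W) continue;
            std::memcpy(dst0 + n * HW + j * H + i_lo,
                        src0 + n * HW + sj * H + i_lo + si0,
                        (i_hi - i_lo) * sizeof(double));
          }
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add patch gradients back onto the input.
static void col2im_add(const arma::mat& dP, arma::mat& dx,
                       const int H, const int W, const int N, const int k) {
  const int C = dx.n_cols, p = (k - 1) / 2, HW = H * W;
  int off = 0;
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di, ++off) {
      const int si0 = di - p, sj0 = dj - p;
      const int i_lo = std::max(0, -si0), i_hi = std::min(H, H - si0);
      if (i_hi <= i_lo) continue;
      for (int c = 0; c < C; ++c) {
        const double* gsrc0 = dP.colptr(off * C + c);
        double* dst0 = dx.colptr(c);
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int sj = j + sj0;
            if (sj < 0 || sj >= W) continue;
            const double* gsrc = gsrc0 + n * HW + j * H;
            double* dst = dst0 + n * HW + sj * H + si0;
            for (int i = i_lo; i < i_hi; ++i) dst[i] += gsrc[i];
          }
        }
      }
    }
  }
}

// Forward convolution with optional fused ReLU. Returns the output feature
// map plus an external pointer to the im2col patch matrix, which the
// autodiff layer hands back to the backward kernel so patches are built
// exactly once per step.
// [[Rcpp::export]]
List conv2d_forward_cpp(const arma::mat& x, const arma::mat& w,
                        const arma::vec& b, const int H, const int W,
                        const int N, const int k, const bool keep_patches,
                        const bool relu) {
  XPtr<arma::mat> P(new arma::mat(x.n_rows,
                                  (arma::uword)(k * k) * x.n_cols,
                                  arma::fill::zeros));
  im2col_fill(x, *P, H, W, N, k);
  arma::mat out = (*P) * w;
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (!keep_patches) P->reset();
  return List::create(Named("out") = out, Named("P") = P);
}

// Backward of (optionally ReLU-fused) convolution. When the forward pass
// applied a ReLU, `out` is its post-activation output and the incoming
// gradient is gated by out > 0 (the subgradient at exactly 0 is taken as 0).
// [[Rcpp::export]]
List conv2d_backward_cpp(SEXP P_ptr, const arma::mat& w, const arma::mat& g,
                         const arma::mat& out, const int Cin, const int H,
                         const int W, const int N, const int k,
                         const bool need_dx, const bool need_dw,
                         const bool relu) {
  List res;
  arma::mat g2;
  const arma::mat* gp = &g;
  if (relu) {
    g2 = g;
    g2.elem(arma::find(out <= 0)).zeros();
    gp = &g2;
  }
  if (need_dw) {
    XPtr<arma::mat> P(P_ptr);
    res["dW"] = arma::mat(P->t() * (*gp));
    res["db"] = arma::vec(arma::sum(*gp, 0).t());
  }
  if (need_dx) {
    arma::mat dP = (*gp) * w.t();
    arma::mat dx(g.n_rows, (arma::uword)Cin, arma::fill::zeros);
    col2im_add(dP, dx, H, W, N, k);
    res["dx"] = dx;
  }
  return res;
}
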