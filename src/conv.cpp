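// Convolution primitives for the package's compact network engine.
// Tensors are R arrays in (H, W, C) layout (column-major); weights are
// (k, k, Cin, Cout). Forward/backward are implemented as im2col + GEMM,
// with pointer-level loops in the gather/scatter steps (they dominate the
// runtime at the small feature-map sizes this engine targets).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// reflect index into [0, n) without repeating the edge sample
inline int reflect_idx(int q, int n) {
  if (q < 0) q = -q;
  if (q >= n) q = 2 * n - 2 - q;
  return q;
}

arma::cube pad_input(const arma::cube& x, int p, bool reflect) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  arma::cube xp(Hp, Wp, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.slice_memptr(c);
    double* dst = xp.slice_memptr(c);
    for (int j = 0; j < W; ++j) {
      std::memcpy(dst + p + (size_t)(j + p) * Hp, src + (size_t)j * H,
                  sizeof(double) * H);
    }
    if (reflect) {
      for (int j = -p; j < W + p; ++j) {
        for (int i = -p; i < H + p; ++i) {
          if (i >= 0 && i < H && j >= 0 && j < W) continue;
          dst[(i + p) + (size_t)(j + p) * Hp] =
            src[reflect_idx(i, H) + (size_t)reflect_idx(j, W) * H];
        }
      }
    }
  }
  return xp;
}

arma::mat im2col(const arma::cube& xp, int k, int s, int cin,
                 int Ho, int Wo) {
  const int Hp = xp.n_rows;
  arma::mat M(k * k * cin, (size_t)Ho * Wo);
  const double* base = xp.memptr();
  const size_t slice_sz = (size_t)Hp * xp.n_cols;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      double* dst = M.colptr(io + (size_t)Ho * jo);
      for (int c = 0; c < cin; ++c) {
        const double* sl = base + c * slice_sz;
        for (int kj = 0; kj < k; ++kj) {
          const double* src = sl + (size_t)(jo * s + kj) * Hp + io * s;
          std::memcpy(dst + k * (kj + k * c), src, sizeof(double) * k);
        }
      }
    }
  }
  return M;
}

arma::mat weights_matrix(const arma::cube& w_flat, int k, int cin, int cout) {
  // w_flat is (k, k, cin*cout); rows of the result are (ki, kj, ci)
  arma::mat Wm(k * k * cin, cout);
  for (int co = 0; co < cout; ++co) {
    double* dst = Wm.colptr(co);
    for (int ci = 0; ci < cin; ++ci) {
      const double* src = w_flat.slice_memptr(ci + cin * co);
      std::memcpy(dst + k * k * ci, src, sizeof(double) * k * k);
    }
  }
  return Wm;
}

} // namespace

// [[Rcpp::export]]
arma::cube conv2d_forward_cpp(const arma::cube& x, const arma::cube& w_flat,
                              const arma::vec& bias, int k, int cin, int cout,
                              int stride, int pad, bool reflect) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube xp = pad_input(x, pad, reflect);
  arma::mat M = im2col(xp, k, stride, cin, Ho, Wo);
  arma::mat Wm = weights_matrix(w_flat, k, cin, cout);
  arma::mat out = M.t() * Wm;           // (Ho*Wo) x cout
  out.each_row() += bias.t();
  arma::cube y(Ho, Wo, cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(const arma::cube& x, const arma::cube& w_flat,
                         const arma::cube& gy, int k, int cin, int cout,
                         int stride, int pad, bool reflect) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  arma::cube xp = pad_input(x, pad, reflect);
  arma::mat M = im2col(xp, k, stride, cin, Ho, Wo);

  arma::mat Gm(const_cast<double*>(gy.memptr()), (size_t)Ho * Wo, cout,
               false, true);
  arma::vec gb = arma::sum(Gm, 0).t();
  arma::mat gWm = M * Gm;               // (k*k*cin) x cout
  arma::mat Wm = weights_matrix(w_flat, k, cin, cout);
  arma::mat gM = Wm * Gm.t();           // (k*k*cin) x (Ho*Wo)

  // scatter-add back into the padded grid, then fold the padding
  arma::cube gxp(Hp, Wp, cin, arma::fill::zeros);
  double* gbase = gxp.memptr();
  const size_t slice_sz = (size_t)Hp * Wp;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const double* src = gM.colptr(io + (size_t)Ho * jo);
      for (int c = 0; c < cin; ++c) {
        double* sl = gbase + c * slice_sz;
        for (int kj = 0; kj < k; ++kj) {
          double* dst = sl + (size_t)(jo * stride + kj) * Hp + io * stride;
          const double* s2 = src + k * (kj + k * c);
          for (int ki = 0; ki < k; ++ki) dst[ki] += s2[ki];
        }
      }
    }
  }
  arma::cube gx(H, W, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* src = gxp.slice_memptr(c);
    double* dst = gx.slice_memptr(c);
    for (int j = 0; j < W; ++j) {
      const double* col = src + pad + (size_t)(j + pad) * Hp;
      double* dcol = dst + (size_t)j * H;
      for (int i = 0; i < H; ++i) dcol[i] += col[i];
    }
    if (reflect && pad > 0) {
      for (int j = -pad; j < W + pad; ++j) {
        for (int i = -pad; i < H + pad; ++i) {
          if (i >= 0 && i < H && j >= 0 && j < W) continue;
          const double g = src[(i + pad) + (size_t)(j + pad) * Hp];
          if (g != 0.0)
            dst[reflect_idx(i, H) + (size_t)reflect_idx(j, W) * H] += g;
        }
      }
    }
  }
  arma::cube gw(k, k, cin * cout);
  for (int co = 0; co < cout; ++co) {
    const double* src = gWm.colptr(co);
    for (int ci = 0; ci < cin; ++ci) {
      std::memcpy(gw.slice_memptr(ci + cin * co), src + k * k * ci,
                  sizeof(double) * k * k);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
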