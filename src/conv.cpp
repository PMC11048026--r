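// 3x3 same-size (zero-padded) convolution primitives for the small model
// observer networks. Batches are matrices with one vectorized image per
// column; an image with C channels is stored column-major as
// index = r + H*c + H*W*ch. Weights are (9*C_in) x F with patch order
// row = ch*9 + (dc+1)*3 + (dr+1). Convolutions are lowered to im2col + GEMM
// so the heavy lifting runs through BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_one(const double* x, int H, int W, int C, mat& P) {
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = x + (size_t)H * W * ch;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int col = ch * 9 + (dc + 1) * 3 + (dr + 1);
        double* pcol = P.colptr(col);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) {
            for (int r = 0; r < H; ++r) pcol[r + (size_t)H * c] = 0.0;
            continue;
          }
          const double* xcc = xc + (size_t)H * cc;
          for (int r = 0; r < H; ++r) {
            int rr = r + dr;
            pcol[r + (size_t)H * c] = (rr >= 0 && rr < H) ? xcc[rr] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const mat& P, int H, int W, int C, double* gx) {
  for (int ch = 0; ch < C; ++ch) {
    double* gc = gx + (size_t)H * W * ch;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int col = ch * 9 + (dc + 1) * 3 + (dr + 1);
        const double* pcol = P.colptr(col);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          double* gcc = gc + (size_t)H * cc;
          for (int r = 0; r < H; ++r) {
            int rr = r + dr;
            if (rr >= 0 && rr < H) gcc[rr] += pcol[r + (size_t)H * c];
          }
        }
      }
    }
  }
}

// x: (H*W*Cin) x B, w: (9*Cin) x F, b: F  ->  (H*W*F) x B
// act: 0 = linear, 1 = LeakyReLU fused into the output
// [[Rcpp::export(name = ".conv3x3_forward")]]
arma::mat conv3x3_forward(const arma::mat& x, const arma::mat& w,
                          const arma::vec& b, int H, int W, int Cin,
                          int act = 0, double slope = 0.01) {
  const int B = x.n_cols, F = w.n_cols;
  mat out((size_t)H * W * F, B);
  mat P((size_t)H * W, 9 * Cin);
  for (int i = 0; i < B; ++i) {
    im2col_one(x.colptr(i), H, W, Cin, P);
    mat y = P * w; // (H*W) x F
    y.each_row() += b.t();
    double* o = out.colptr(i);
    const double* yy = y.memptr();
    const size_t n = y.n_elem;
    if (act == 1) {
      for (size_t k = 0; k < n; ++k) o[k] = yy[k] > 0 ? yy[k] : slope * yy[k];
    } else {
      std::memcpy(o, yy, sizeof(double) * n);
    }
  }
  return out;
}

// gradients wrt input, weights, bias given upstream grad g (already through
// any fused activation) : (H*W*F) x B. need_gx = false skips the input
// gradient (first layer).
// [[Rcpp::export(name = ".conv3x3_backward")]]
Rcpp::List conv3x3_backward(const arma::mat& x, const arma::mat& w,
                            const arma::mat& gy, int H, int W, int Cin,
                            bool need_gx = true) {
  const int B = x.n_cols, F = w.n_cols;
  const size_t HW = (size_t)H * W;
  mat gx(need_gx ? HW * Cin : 0, need_gx ? B : 0, fill::zeros);
  mat gw(9 * Cin, F, fill::zeros);
  vec gb(F, fill::zeros);
  mat P(HW, 9 * Cin);
  for (int i = 0; i < B; ++i) {
    im2col_one(x.colptr(i), H, W, Cin, P);
    const mat G(const_cast<double*>(gy.colptr(i)), HW, F, false, true);
    gw += P.t() * G;
    gb += sum(G, 0).t();
    if (need_gx) {
      mat GP = G * w.t(); // (H*W) x (9*Cin)
      col2im_one(GP, H, W, Cin, gx.colptr(i));
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// In-place Adam parameter update (p, m, v modified; g untouched).
// wd is the full weight-decay gradient coefficient (2*lambda), applied to p.
// bc1/bc2 are the bias-correction factors 1 - beta^t.
// [[Rcpp::export(name = ".adam_update")]]
void adam_update(Rcpp::NumericVector p, Rcpp::NumericVector m,
                 Rcpp::NumericVector v, Rcpp::NumericVector g,
                 double lr, double b1, double b2, double eps,
                 double bc1, double bc2, double wd) {
  R_xlen_t n = p.size();
  double* pp = p.begin();
  double* mm = m.begin();
  double* vv = v.begin();
  const double* gg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = gg[i] + wd * pp[i];
    mm[i] = b1 * mm[i] + (1.0 - b1) * gi;
    vv[i] = b2 * vv[i] + (1.0 - b2) * gi * gi;
    pp[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
Rcpp::NumericMatrix lrelu_fwd(const Rcpp::NumericMatrix& z, double slope) {
  Rcpp::NumericMatrix out(z.nrow(), z.ncol());
  R_xlen_t n = z.size();
  const double* zz = z.begin();
  double* oo = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) oo[i] = zz[i] > 0 ? zz[i] : slope * zz[i];
  return out;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
Rcpp::NumericMatrix lrelu_bwd(const Rcpp::NumericMatrix& z,
                              const Rcpp::NumericMatrix& g, double slope) {
  Rcpp::NumericMatrix out(z.nrow(), z.ncol());
  R_xlen_t n = z.size();
  const double* zz = z.begin();
  const double* gg = g.begin();
  double* oo = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) oo[i] = zz[i] > 0 ? gg[i] : slope * gg[i];
  return out;
}
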