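// Dilated 3x3 convolution primitives for the spheroid segmentation
// network.  Layout: activations are H x W x C cubes; a layer's weights
// are a (9*Cin) x Cout matrix whose rows are ordered channel-major,
// within channel by (dj, di) offset in {-1,0,1} x {-1,0,1}
// (column offset outer, row offset inner).  Same-padding with zeros.
//
// Convolutions are computed by direct accumulation over the 9 shifted
// padded views rather than im2col: for these channel counts the GEMM
// is tiny and the im2col matrix would dominate the memory traffic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static std::vector<mat> pad_channels(const cube& x, const int d) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  std::vector<mat> pad(C);
  for (int c = 0; c < C; ++c) {
    pad[c].zeros(H + 2 * d, Wd + 2 * d);
    pad[c].submat(d, d, d + H - 1, d + Wd - 1) = x.slice(c);
  }
  return pad;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, const int d,
                     const bool relu = false) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  std::vector<mat> pad = pad_channels(x, d);
  cube y(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    mat acc(H, Wd);
    acc.fill(b(co));
    for (int ci = 0; ci < Cin; ++ci) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di, ++k) {
          const double w = W(9 * ci + k, co);
          if (w != 0.0)
            acc += w * pad[ci].submat(d + di * d, d + dj * d,
                                      d + di * d + H - 1,
                                      d + dj * d + Wd - 1);
        }
      }
    }
    if (relu)
      acc.transform([](double v) { return v > 0.0 ? v : 0.0; });
    y.slice(co) = acc;
  }
  return y;
}

// Backward pass of one dilated conv layer.  When act has the same
// size as gy it holds this layer's post-ReLU output and gy is masked
// by act > 0 first (fused ReLU backward); pass a 0x0x0 cube to skip.
// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& W,
                     arma::cube gy, const arma::cube& act,
                     const int d) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  if (act.n_elem == gy.n_elem) {
    for (uword i = 0; i < gy.n_elem; ++i)
      if (act(i) <= 0.0) gy(i) = 0.0;
  }
  std::vector<mat> pad = pad_channels(x, d);
  mat gW(9 * Cin, Cout);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = accu(gy.slice(co));
    for (int ci = 0; ci < Cin; ++ci) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di, ++k) {
          gW(9 * ci + k, co) =
            accu(pad[ci].submat(d + di * d, d + dj * d,
                                d + di * d + H - 1,
                                d + dj * d + Wd - 1) % gy.slice(co));
        }
      }
    }
  }
  cube gx(H, Wd, Cin);
  mat acc(H + 2 * d, Wd + 2 * d);
  for (int ci = 0; ci < Cin; ++ci) {
    acc.zeros();
    for (int co = 0; co < Cout; ++co) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di, ++k) {
          const double w = W(9 * ci + k, co);
          if (w != 0.0)
            acc.submat(d + di * d, d + dj * d,
                       d + di * d + H - 1, d + dj * d + Wd - 1) +=
              w * gy.slice(co);
        }
      }
    }
    gx.slice(ci) = acc.submat(d, d, d + H - 1, d + Wd - 1);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
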