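// Low-level tensor ops for the segmentation networks: same-padding 2-D
// convolution (via im2col), 2x2 max pooling, and integer-factor bilinear
// upsampling with its exact adjoint. Tensors are H x W x C cubes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column order of the patch matrix: channel slowest, then kernel dy, then
// kernel dx. Must match the weight layout used on the R side.
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  arma::mat M(static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * C,
              arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int dx = -p; dx <= p; ++dx) {
      for (int dy = -p; dy <= p; ++dy) {
        // destination pixel (i,j) reads source (i+dy, j+dx)
        int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        arma::mat shifted(H, W, arma::fill::zeros);
        if (i1 > i0 && j1 > j0) {
          shifted.submat(i0, j0, i1 - 1, j1 - 1) =
            s.submat(i0 + dy, j0 + dx, i1 - 1 + dy, j1 - 1 + dx);
        }
        M.col(col++) = arma::vectorise(shifted);
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter patch-matrix gradients back onto the image.
static arma::cube col2im(const arma::mat& G, int H, int W, int C, int k) {
  const int p = k / 2;
  arma::cube gx(H, W, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dx = -p; dx <= p; ++dx) {
      for (int dy = -p; dy <= p; ++dy) {
        arma::mat g = arma::reshape(G.col(col++), H, W);
        int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        if (i1 > i0 && j1 > j0) {
          gx.slice(c).submat(i0 + dy, j0 + dx, i1 - 1 + dy, j1 - 1 + dx) +=
            g.submat(i0, j0, i1 - 1, j1 - 1);
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = "cpp_conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat M = im2col(x, k);
  arma::mat Y = M * w;
  Y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c) out.slice(c) = arma::reshape(Y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = "cpp_conv2d_bw")]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
               int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat G(static_cast<size_t>(H) * W, Cout);
  for (int c = 0; c < Cout; ++c) G.col(c) = arma::vectorise(gy.slice(c));
  arma::mat M = im2col(x, k);
  arma::mat gw = M.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im(G * w.t(), H, W, Cin, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = "cpp_maxpool_fw")]]
List maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // 0..3: (dy, dx) = (i%2, i/2)
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        unsigned int bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            double v = x(2 * i + dy, 2 * j + dx, c);
            if (v > best) { best = v; bi = dy + 2 * dx; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool_bw")]]
arma::cube maxpool_bw(const arma::cube& gy, const arma::ucube& idx,
                      int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        unsigned int b = idx(i, j, c);
        gx(2 * i + (b % 2), 2 * j + (b / 2), c) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// Bilinear upsampling by integer factor s, half-pixel-centre convention
// (src = (dst + 0.5)/s - 0.5), clamped at borders. Shift-invariant in
// blocks of s, so padding by multiples of s only translates the output.
// [[Rcpp::export(name = "cpp_upsample_fw")]]
arma::cube upsample_fw(const arma::cube& x, int s) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  const int H = h * s, W = w * s;
  arma::vec i0(H), i1(H), iw(H), j0(W), j1(W), jw(W);
  for (int i = 0; i < H; ++i) {
    double src = (i + 0.5) / s - 0.5;
    double f = std::floor(src);
    double t = src - f;
    int a = std::max(0, std::min(h - 1, (int)f));
    int b = std::max(0, std::min(h - 1, (int)f + 1));
    i0[i] = a; i1[i] = b; iw[i] = (f < 0) ? 0.0 : ((f + 1 > h - 1) ? 0.0 : t);
  }
  for (int j = 0; j < W; ++j) {
    double src = (j + 0.5) / s - 0.5;
    double f = std::floor(src);
    double t = src - f;
    int a = std::max(0, std::min(w - 1, (int)f));
    int b = std::max(0, std::min(w - 1, (int)f + 1));
    j0[j] = a; j1[j] = b; jw[j] = (f < 0) ? 0.0 : ((f + 1 > w - 1) ? 0.0 : t);
  }
  arma::cube y(H, W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < W; ++j) {
      int ja = j0[j], jb = j1[j]; double tj = jw[j];
      for (int i = 0; i < H; ++i) {
        int ia = i0[i], ib = i1[i]; double ti = iw[i];
        y(i, j, c) = (1 - ti) * (1 - tj) * xs(ia, ja) +
                     ti * (1 - tj) * xs(ib, ja) +
                     (1 - ti) * tj * xs(ia, jb) +
                     ti * tj * xs(ib, jb);
      }
    }
  }
  return y;
}

// Exact adjoint of upsample_fw.
// [[Rcpp::export(name = "cpp_upsample_bw")]]
arma::cube upsample_bw(const arma::cube& gy, int s, int h, int w) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  arma::cube gx(h, w, C, arma::fill::zeros);
  std::vector<int> i0(H), i1(H); std::vector<double> iw(H);
  std::vector<int> j0(W), j1(W); std::vector<double> jw(W);
  for (int i = 0; i < H; ++i) {
    double src = (i + 0.5) / s - 0.5;
    double f = std::floor(src);
    double t = src - f;
    i0[i] = std::max(0, std::min(h - 1, (int)f));
    i1[i] = std::max(0, std::min(h - 1, (int)f + 1));
    iw[i] = (f < 0) ? 0.0 : ((f + 1 > h - 1) ? 0.0 : t);
  }
  for (int j = 0; j < W; ++j) {
    double src = (j + 0.5) / s - 0.5;
    double f = std::floor(src);
    double t = src - f;
    j0[j] = std::max(0, std::min(w - 1, (int)f));
    j1[j] = std::max(0, std::min(w - 1, (int)f + 1));
    jw[j] = (f < 0) ? 0.0 : ((f + 1 > w - 1) ? 0.0 : t);
  }
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double g = gy(i, j, c);
        double ti = iw[i], tj = jw[j];
        gx(i0[i], j0[j], c) += (1 - ti) * (1 - tj) * g;
        gx(i1[i], j0[j], c) += ti * (1 - tj) * g;
        gx(i0[i], j1[j], c) += (1 - ti) * tj * g;
        gx(i1[i], j1[j], c) += ti * tj * g;
      }
    }
  }
  return gx;
}
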