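// Convolution / pooling primitives for the seeded encoder-decoder
// segmentation network. Tensors are H x W x C arma::cubes at the R
// interface; convolution arithmetic runs in single precision (the usual
// CNN precision, and twice the GEMM throughput of double) with a fixed
// accumulation order, so results are deterministic on a fixed platform.
// 3x3 convolutions use zero padding and an im2col + GEMM formulation, with
// weights stored as a (9*C_in) x C_out matrix whose rows are ordered
// (dr, dc, channel) with dr, dc in {-1, 0, 1} scanned row-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static fmat im2col3(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat out(H * W, 9 * C, fill::zeros);
  uword col = 0;
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (uword ch = 0; ch < C; ++ch, ++col) {
        const fmat& sl = x.slice(ch);
        // destination rows correspond to output pixel (r, c) at linear
        // index r + c * H; source pixel is (r + dr, c + dc) when in range
        const int r0 = std::max(0, -dr), r1 = std::min((int)H, (int)H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min((int)W, (int)W - dc);
        for (int c2 = c0; c2 < c1; ++c2) {
          const float* src = sl.colptr(c2 + dc) + (r0 + dr);
          float* dst = out.colptr(col) + (c2 * H + r0);
          std::copy(src, src + (r1 - r0), dst);
        }
      }
    }
  }
  return out;
}

static fcube col2im3(const fmat& cols, uword H, uword W, uword C) {
  fcube out(H, W, C, fill::zeros);
  uword col = 0;
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (uword ch = 0; ch < C; ++ch, ++col) {
        fmat& sl = out.slice(ch);
        const int r0 = std::max(0, -dr), r1 = std::min((int)H, (int)H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min((int)W, (int)W - dc);
        for (int c2 = c0; c2 < c1; ++c2) {
          const float* src = cols.colptr(col) + (c2 * H + r0);
          float* dst = sl.colptr(c2 + dc) + (r0 + dr);
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return out;
}

static fcube to_f(const cube& x) { return conv_to<fcube>::from(x); }
static cube to_d(const fcube& x) { return conv_to<cube>::from(x); }

// Forward 3x3 convolution. Returns the output cube and (for reuse in the
// backward pass) the im2col workspace of the input.
// [[Rcpp::export]]
Rcpp::List cpp_conv3_fwd_ws(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols, F = w.n_cols;
  fmat cols = im2col3(to_f(x));
  fmat wf = conv_to<fmat>::from(w);
  frowvec bf = conv_to<frowvec>::from(b.t());
  fmat y = cols * wf;
  y.each_row() += bf;
  cube out(H, W, F);
  for (uword f = 0; f < F; ++f)
    out.slice(f) = conv_to<mat>::from(reshape(y.col(f), H, W));
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  Rcpp::List r = cpp_conv3_fwd_ws(x, w, b);
  return Rcpp::as<arma::cube>(r["y"]);
}

// Backward 3x3 convolution, reusing the forward im2col workspace (`cols`,
// a float matrix as returned by cpp_conv3_fwd_ws). `need_gx` skips the
// input-gradient GEMM for the first layer.
// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd_ws(const arma::fmat& cols, const arma::mat& w,
                            const arma::cube& gy, int n_in_channels,
                            bool need_gx = true) {
  const uword H = gy.n_rows, W = gy.n_cols, F = gy.n_slices;
  const uword C = (uword)n_in_channels;
  fmat gy_mat(H * W, F);
  for (uword f = 0; f < F; ++f)
    gy_mat.col(f) = conv_to<fvec>::from(vectorise(gy.slice(f)));
  fmat gw = cols.t() * gy_mat;
  frowvec gb = sum(gy_mat, 0);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("gw") = conv_to<mat>::from(gw),
      Rcpp::Named("gb") = conv_to<vec>::from(gb.t()),
      Rcpp::Named("gx") = R_NilValue);
  if (need_gx) {
    fmat wf = conv_to<fmat>::from(w);
    fmat gcols = gy_mat * wf.t();
    out["gx"] = to_d(col2im3(gcols, H, W, C));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword h = H / 2, w = W / 2;
  cube y(h, w, C);
  ucube idx(h, w, C); // linear index within the slice of the argmax
  for (uword ch = 0; ch < C; ++ch) {
    const mat& sl = x.slice(ch);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        uword r = 2 * i, c = 2 * j;
        double best = sl(r, c);
        uword bi = r + c * H;
        if (sl(r + 1, c) > best) { best = sl(r + 1, c); bi = r + 1 + c * H; }
        if (sl(r, c + 1) > best) { best = sl(r, c + 1); bi = r + (c + 1) * H; }
        if (sl(r + 1, c + 1) > best) { best = sl(r + 1, c + 1); bi = r + 1 + (c + 1) * H; }
        y(i, j, ch) = best;
        idx(i, j, ch) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gy, const arma::ucube& idx,
                            int H, int W) {
  const uword C = gy.n_slices;
  cube gx((uword)H, (uword)W, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    mat& g = gx.slice(ch);
    const mat& gyc = gy.slice(ch);
    const umat& ic = idx.slice(ch);
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i)
        g(ic(i, j)) += gyc(i, j);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword ch = 0; ch < C; ++ch) {
    const mat& sl = x.slice(ch);
    mat& o = y.slice(ch);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const double v = sl(i, j);
        o(2 * i, 2 * j) = v;
        o(2 * i + 1, 2 * j) = v;
        o(2 * i, 2 * j + 1) = v;
        o(2 * i + 1, 2 * j + 1) = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (uword ch = 0; ch < C; ++ch) {
    const mat& g = gy.slice(ch);
    mat& o = gx.slice(ch);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        o(i, j) = g(2 * i, 2 * j) + g(2 * i + 1, 2 * j) +
                  g(2 * i, 2 * j + 1) + g(2 * i + 1, 2 * j + 1);
  }
  return gx;
}
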