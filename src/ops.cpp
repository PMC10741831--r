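// Low-level numerical kernels for the motion-simulation network.
//
// Conventions shared with the R side:
//  * feature maps are arma::cube (H, W, C), matching R arrays dim c(H, W, C)
//  * 3x3 conv weights are (9*Cin) x Cout matrices; row index k + 9*ci with
//    k = (di+1) + 3*(dj+1), di/dj row/col offsets in {-1,0,1} ("same" padding)
//  * displacement fields are cubes (H, W, 2): slice 0 = u_x (column
//    displacement), slice 1 = u_y (row displacement), pixel units
//  * sampling uses border clamping; gradients w.r.t. clamped coordinates are 0

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = (di + 1) + 3 * (dj + 1) + 9 * c;
        // valid output range for this offset
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        arma::mat view(cols.colptr(col), H, W, false, true);
        view.submat(i0, j0, i1, j1) =
          x.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = "cpp_conv3_fwd")]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col3(x) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = "cpp_conv3_bwd")]]
List conv3_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dymat(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dymat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat cols = im2col3(x);
  arma::mat dw = cols.t() * dymat;
  arma::vec db = arma::sum(dymat, 0).t();
  arma::mat dcols = dymat * w.t();
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = (di + 1) + 3 * (dj + 1) + 9 * c;
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        arma::mat view(dcols.colptr(col), H, W, false, true);
        dx.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
          view.submat(i0, j0, i1, j1);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and 1-based linear argmax
// indices into the input cube (for the backward pass).
// [[Rcpp::export(name = "cpp_maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0, bj = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const double v = x(2 * i + a, 2 * j + b, c);
            if (v > best) { best = v; bi = 2 * i + a; bj = 2 * j + b; }
          }
        y(i, j, c) = best;
        idx[p++] = 1 + bi + H * bj + H * W * c;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::cube& dy, const IntegerVector& idx,
                        int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* src = dy.memptr();
  double* dst = dx.memptr();
  for (int p = 0; p < idx.size(); ++p)
    dst[idx[p] - 1] += src[p];
  return dx;
}

// 2x2 transposed convolution, stride 2 ("de-convolution" upsampling).
// Weights: cube (Cin, Cout, 4), slice k = a + 2*b for output offset (a, b).
// [[Rcpp::export(name = "cpp_tconv2_fwd")]]
arma::cube tconv2_fwd(const arma::cube& x, const arma::cube& w,
                      const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  arma::mat xmat(H * W, Cin);
  for (int c = 0; c < Cin; ++c)
    xmat.col(c) = arma::vectorise(x.slice(c));
  arma::cube y(2 * H, 2 * W, Cout);
  for (int bb = 0; bb < 2; ++bb)
    for (int aa = 0; aa < 2; ++aa) {
      arma::mat yk = xmat * w.slice(aa + 2 * bb);
      yk.each_row() += b.t();
      for (int c = 0; c < Cout; ++c)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + aa, 2 * j + bb, c) = yk(i + H * j, c);
    }
  return y;
}

// [[Rcpp::export(name = "cpp_tconv2_bwd")]]
List tconv2_bwd(const arma::cube& x, const arma::cube& w, const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  arma::mat xmat(H * W, Cin);
  for (int c = 0; c < Cin; ++c)
    xmat.col(c) = arma::vectorise(x.slice(c));
  arma::mat dxmat(H * W, Cin, arma::fill::zeros);
  arma::cube dw(Cin, Cout, 4, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int bb = 0; bb < 2; ++bb)
    for (int aa = 0; aa < 2; ++aa) {
      const int k = aa + 2 * bb;
      arma::mat dyk(H * W, Cout);
      for (int c = 0; c < Cout; ++c)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dyk(i + H * j, c) = dy(2 * i + aa, 2 * j + bb, c);
      dxmat += dyk * w.slice(k).t();
      dw.slice(k) = xmat.t() * dyk;
      db += arma::sum(dyk, 0).t();
    }
  arma::cube dx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = arma::reshape(dxmat.col(c), H, W);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear / nearest spatial sampling with border clamping.
// Output pixel (i, j) samples the input at row i + u_y(i,j), col j + u_x(i,j).
// [[Rcpp::export(name = "cpp_warp_fwd")]]
arma::mat warp_fwd(const arma::mat& img, const arma::cube& u, bool nearest) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double sr = i + u(i, j, 1);
      double sc = j + u(i, j, 0);
      sr = std::min(std::max(sr, 0.0), double(H - 1));
      sc = std::min(std::max(sc, 0.0), double(W - 1));
      if (nearest) {
        out(i, j) = img(int(std::lround(sr)), int(std::lround(sc)));
      } else {
        int r0 = std::min(int(std::floor(sr)), H - 2);
        int c0 = std::min(int(std::floor(sc)), W - 2);
        if (r0 < 0) r0 = 0;
        if (c0 < 0) c0 = 0;
        const double fr = sr - r0, fc = sc - c0;
        out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0)
                  + fr * (1 - fc) * img(r0 + 1, c0)
                  + (1 - fr) * fc * img(r0, c0 + 1)
                  + fr * fc * img(r0 + 1, c0 + 1);
      }
    }
  return out;
}

// Backward pass of bilinear warping: gradients w.r.t. the image and the
// displacement field. Clamped samples get zero coordinate gradient.
// [[Rcpp::export(name = "cpp_warp_bwd")]]
List warp_bwd(const arma::mat& img, const arma::cube& u, const arma::mat& dy) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat dimg(H, W, arma::fill::zeros);
  arma::cube du(H, W, 2, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double g = dy(i, j);
      if (g == 0.0) continue;
      double sr = i + u(i, j, 1);
      double sc = j + u(i, j, 0);
      const bool clamp_r = (sr <= 0.0) || (sr >= H - 1);
      const bool clamp_c = (sc <= 0.0) || (sc >= W - 1);
      sr = std::min(std::max(sr, 0.0), double(H - 1));
      sc = std::min(std::max(sc, 0.0), double(W - 1));
      int r0 = std::min(int(std::floor(sr)), H - 2);
      int c0 = std::min(int(std::floor(sc)), W - 2);
      if (r0 < 0) r0 = 0;
      if (c0 < 0) c0 = 0;
      const double fr = sr - r0, fc = sc - c0;
      dimg(r0, c0)         += g * (1 - fr) * (1 - fc);
      dimg(r0 + 1, c0)     += g * fr * (1 - fc);
      dimg(r0, c0 + 1)     += g * (1 - fr) * fc;
      dimg(r0 + 1, c0 + 1) += g * fr * fc;
      if (!clamp_r)
        du(i, j, 1) = g * ((1 - fc) * (img(r0 + 1, c0) - img(r0, c0))
                           + fc * (img(r0 + 1, c0 + 1) - img(r0, c0 + 1)));
      if (!clamp_c)
        du(i, j, 0) = g * ((1 - fr) * (img(r0, c0 + 1) - img(r0, c0))
                           + fr * (img(r0 + 1, c0 + 1) - img(r0 + 1, c0)));
    }
  return List::create(_["dimg"] = dimg, _["du"] = du);
}

// Connected-component labelling of a logical 2D/3D array (4- / 6-neighbour).
// Returns integer labels 1..K in scan order, 0 for background.
// [[Rcpp::export(name = "cpp_label_components")]]
IntegerVector label_components(const LogicalVector& mask,
                               const IntegerVector& dims) {
  const int nd = dims.size();
  const int H = dims[0], W = dims[1], D = (nd > 2) ? dims[2] : 1;
  const int n = H * W * D;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int d = p / (H * W);
      const int r = p % H;
      const int c = (p / H) % W;
      const int nb[6][3] = {{r - 1, c, d}, {r + 1, c, d}, {r, c - 1, d},
                            {r, c + 1, d}, {r, c, d - 1}, {r, c, d + 1}};
      for (int k = 0; k < 6; ++k) {
        const int rr = nb[k][0], cc = nb[k][1], dd = nb[k][2];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W || dd < 0 || dd >= D)
          continue;
        const int q = rr + H * cc + H * W * dd;
        if (mask[q] && labels[q] == 0) {
          labels[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
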