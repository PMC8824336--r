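// Minimal convolutional kernels for the segmentation network: 3x3 'same'
// convolution via im2col + gemm, 2x2 max pooling, and nearest 2x upsampling,
// each with its backward pass. Arrays are (h, w, channels), column-major,
// matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Patch matrix: row = pixel (column-major over h x w), column block per input
// channel, 9 offsets per block, zero padding outside the image.
static mat im2col3(const cube& x) {
  const uword h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  mat out(h * w, 9 * cin, fill::zeros);
  uword col = 0;
  for (uword ci = 0; ci < cin; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat s(h, w, fill::zeros);
        const int r0 = std::max(0, -dy), r1 = std::min((int)h, (int)h - dy);
        const int c0 = std::max(0, -dx), c1 = std::min((int)w, (int)w - dx);
        if (r1 > r0 && c1 > c0)
          s.submat(r0, c0, r1 - 1, c1 - 1) =
            x.slice(ci).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
        out.col(col) = vectorise(s);
        ++col;
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch-matrix gradients back to pixels.
static cube col2im3(const mat& g, uword h, uword w, uword cin) {
  cube dx_out(h, w, cin, fill::zeros);
  uword col = 0;
  for (uword ci = 0; ci < cin; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat gm(const_cast<double*>(g.colptr(col)), h, w, false, true);
        const int r0 = std::max(0, -dy), r1 = std::min((int)h, (int)h - dy);
        const int c0 = std::max(0, -dx), c1 = std::min((int)w, (int)w - dx);
        if (r1 > r0 && c1 > c0)
          dx_out.slice(ci).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx) +=
            gm.submat(r0, c0, r1 - 1, c1 - 1);
        ++col;
      }
    }
  }
  return dx_out;
}

// [[Rcpp::export]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const uword h = x.n_rows, w = x.n_cols, cout_n = W.n_cols;
  mat y = im2col3(x) * W;
  y.each_row() += b.t();
  cube out(h, w, cout_n);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3_backward(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy) {
  const uword h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const uword cout_n = dy.n_slices;
  mat D(const_cast<double*>(dy.memptr()), h * w, cout_n, false, true);
  mat P = im2col3(x);
  mat dW = P.t() * D;
  vec db = sum(D, 0).t();
  cube dx_out = col2im3(D * W.t(), h, w, cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx_out,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Forward keeping the patch matrix as a workspace for the backward pass.
// [[Rcpp::export]]
Rcpp::List conv3_forward_ws(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b) {
  const uword h = x.n_rows, w = x.n_cols, cout_n = W.n_cols;
  mat P = im2col3(x);
  mat y = P * W;
  y.each_row() += b.t();
  cube out(h, w, cout_n);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return Rcpp::List::create(Rcpp::Named("y") = out, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List conv3_backward_ws(const arma::mat& P, const arma::mat& W,
                             const arma::cube& dy, int cin) {
  const uword h = dy.n_rows, w = dy.n_cols, cout_n = dy.n_slices;
  mat D(const_cast<double*>(dy.memptr()), h * w, cout_n, false, true);
  mat dW = P.t() * D;
  vec db = sum(D, 0).t();
  cube dx_out = col2im3(D * W.t(), h, w, (uword)cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx_out,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling; idx stores the in-block winner as di + 2*dj.
// [[Rcpp::export]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const uword h = x.n_rows / 2, w = x.n_cols / 2, c = x.n_slices;
  cube y(h, w, c), idx(h, w, c);
  for (uword k = 0; k < c; ++k)
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, k);
        uword bi = 0;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, k);
            if (v > best) { best = v; bi = di + 2 * dj; }
          }
        y(i, j, k) = best;
        idx(i, j, k) = (double)bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& idx, const arma::cube& dy) {
  const uword h = dy.n_rows, w = dy.n_cols, c = dy.n_slices;
  cube dx_out(2 * h, 2 * w, c, fill::zeros);
  for (uword k = 0; k < c; ++k)
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i) {
        const uword bi = (uword)idx(i, j, k);
        dx_out(2 * i + bi % 2, 2 * j + bi / 2, k) = dy(i, j, k);
      }
  return dx_out;
}

// [[Rcpp::export]]
arma::cube upsample2(const arma::cube& x) {
  const uword h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube y(2 * h, 2 * w, c);
  for (uword k = 0; k < c; ++k)
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i) {
        const double v = x(i, j, k);
        y(2 * i, 2 * j, k) = v;
        y(2 * i + 1, 2 * j, k) = v;
        y(2 * i, 2 * j + 1, k) = v;
        y(2 * i + 1, 2 * j + 1, k) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_backward(const arma::cube& dy) {
  const uword h = dy.n_rows / 2, w = dy.n_cols / 2, c = dy.n_slices;
  cube dx_out(h, w, c);
  for (uword k = 0; k < c; ++k)
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i)
        dx_out(i, j, k) = dy(2 * i, 2 * j, k) + dy(2 * i + 1, 2 * j, k) +
                          dy(2 * i, 2 * j + 1, k) + dy(2 * i + 1, 2 * j + 1, k);
  return dx_out;
}
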