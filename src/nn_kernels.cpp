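// Low-level kernels for the density-regression network: im2col 3x3 "same"
// convolution (zero padding) with fused ReLU and its gradients, 2x2 max
// pooling, and 2x nearest-neighbour upsampling. Feature maps are H x W x C
// arrays; im2col column order is channel-major (channel c occupies columns
// c*9 .. c*9+8, taps ordered dc = -1..1 outer, dr = -1..1 inner) and weight
// matrices must use the same row order. The im2col matrix is rebuilt in the
// backward pass from the cached layer input rather than stored, trading a
// little compute for much less memory traffic.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// zero-copy view of an R numeric array as an arma cube
static cube cube_view(const Rcpp::NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array");
  return cube(const_cast<double*>(v.begin()), d[0], d[1], d[2], false, true);
}

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(H * W, 9 * C);
  mat padded(H + 2, W + 2, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    padded.submat(1, 1, H, W) = x.slice(c);
    uword t = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++t) {
        cols.col(c * 9 + t) =
          vectorise(padded.submat(1 + dr, 1 + dc, H + dr, W + dc));
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
Rcpp::NumericVector conv3x3_forward(Rcpp::NumericVector x,
                                    const arma::mat& w, const arma::vec& b,
                                    bool relu) {
  cube xv = cube_view(x);
  const uword H = xv.n_rows, W = xv.n_cols;
  const uword O = w.n_cols;
  if (w.n_rows != 9 * xv.n_slices)
    Rcpp::stop("weight rows must equal 9 * input channels");
  mat out = im2col3(xv) * w;
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = Rcpp::IntegerVector::create(H, W, O);
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(Rcpp::NumericVector x, const arma::mat& w,
                            Rcpp::NumericVector out,
                            Rcpp::NumericVector grad_out, bool relu) {
  cube xv = cube_view(x);
  const uword H = xv.n_rows, W = xv.n_cols, C = xv.n_slices;
  Rcpp::IntegerVector d = grad_out.attr("dim");
  const uword O = d[2];
  mat go(const_cast<double*>(grad_out.begin()), H * W, O, false, true);
  mat gom;
  if (relu) {
    // the rectifier passed a pixel iff its (post-activation) output is > 0
    mat om(const_cast<double*>(out.begin()), H * W, O, false, true);
    gom = go % (om > 0);
  } else {
    gom = go;
  }
  mat cols = im2col3(xv);
  mat grad_w = cols.t() * gom;
  vec grad_b = sum(gom, 0).t();
  mat grad_cols = gom * w.t();
  cube grad_x(H, W, C);
  mat acc(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    acc.zeros();
    uword t = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++t) {
        acc.submat(1 + dr, 1 + dc, H + dr, W + dc) +=
          reshape(grad_cols.col(c * 9 + t), H, W);
      }
    }
    grad_x.slice(c) = acc.submat(1, 1, H, W);
  }
  return Rcpp::List::create(Rcpp::Named("grad_x") = grad_x,
                            Rcpp::Named("grad_w") = grad_w,
                            Rcpp::Named("grad_b") = grad_b);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_forward(Rcpp::NumericVector x) {
  cube xv = cube_view(x);
  const uword H = xv.n_rows, W = xv.n_cols, C = xv.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("max pooling needs even side lengths");
  const uword h = H / 2, w = W / 2;
  cube out(h, w, C);
  ucube arg(h, w, C);  // linear index into the input slice of the max
  for (uword c = 0; c < C; ++c) {
    const mat& s = xv.slice(c);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        uword r = 2 * i, q = 2 * j;
        uword best = r + H * q;
        double bv = s(r, q);
        if (s(r + 1, q) > bv) { bv = s(r + 1, q); best = r + 1 + H * q; }
        if (s(r, q + 1) > bv) { bv = s(r, q + 1); best = r + H * (q + 1); }
        if (s(r + 1, q + 1) > bv) {
          bv = s(r + 1, q + 1); best = r + 1 + H * (q + 1);
        }
        out(i, j, c) = bv;
        arg(i, j, c) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(Rcpp::NumericVector grad_out,
                             const arma::ucube& arg, int H, int W) {
  cube gv = cube_view(grad_out);
  const uword h = gv.n_rows, w = gv.n_cols, C = gv.n_slices;
  cube grad_x((uword)H, (uword)W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& gs = grad_x.slice(c);
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i)
        gs(arg(i, j, c)) += gv(i, j, c);
  }
  return grad_x;
}

// [[Rcpp::export]]
arma::cube upsample2_forward(Rcpp::NumericVector x) {
  cube xv = cube_view(x);
  const uword H = xv.n_rows, W = xv.n_cols, C = xv.n_slices;
  cube out(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c) {
    const mat& s = xv.slice(c);
    mat& o = out.slice(c);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v = s(i, j);
        o(2 * i, 2 * j) = v;
        o(2 * i + 1, 2 * j) = v;
        o(2 * i, 2 * j + 1) = v;
        o(2 * i + 1, 2 * j + 1) = v;
      }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_backward(Rcpp::NumericVector grad_out) {
  cube gv = cube_view(grad_out);
  const uword H = gv.n_rows / 2, W = gv.n_cols / 2, C = gv.n_slices;
  cube grad_x(H, W, C);
  for (uword c = 0; c < C; ++c) {
    const mat& g = gv.slice(c);
    mat& o = grad_x.slice(c);
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        o(i, j) = g(2 * i, 2 * j) + g(2 * i + 1, 2 * j) +
                  g(2 * i, 2 * j + 1) + g(2 * i + 1, 2 * j + 1);
  }
  return grad_x;
}
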