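// Numerical core: fully convolutional segmenter (forward + backprop),
// box blur, RBF kernel, SMO solver for the soft-margin SVM dual, and a
// gini-split CART forest. All deterministic given the seeds passed in.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// ---------------------------------------------------------------------------
// Fully convolutional segmenter. Internals run in single precision (the
// conventional choice for conv nets, and twice the GEMM throughput of
// doubles); the R interface stays double.
// im2col / col2im for 3x3 zero-padded stride-1 convolution.
// Column-major pixel order: linear index p = r + h*c  (r row, c col).
// ---------------------------------------------------------------------------
static fmat im2col3(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat M(H * W, 9 * C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    const fmat& s = x.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword col = ch * 9 + (uword)((dc + 1) * 3 + (dr + 1));
        for (uword c = 0; c < W; ++c) {
          const long cc = (long)c + dc;
          if (cc < 0 || cc >= (long)W) continue;
          for (uword r = 0; r < H; ++r) {
            const long rr = (long)r + dr;
            if (rr < 0 || rr >= (long)H) continue;
            M(r + H * c, col) = s((uword)rr, (uword)cc);
          }
        }
      }
    }
  }
  return M;
}

static fcube col2im3(const fmat& dM, uword H, uword W, uword C) {
  fcube dx(H, W, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    fmat& s = dx.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword col = ch * 9 + (uword)((dc + 1) * 3 + (dr + 1));
        for (uword c = 0; c < W; ++c) {
          const long cc = (long)c + dc;
          if (cc < 0 || cc >= (long)W) continue;
          for (uword r = 0; r < H; ++r) {
            const long rr = (long)r + dr;
            if (rr < 0 || rr >= (long)H) continue;
            s((uword)rr, (uword)cc) += dM(r + H * c, col);
          }
        }
      }
    }
  }
  return dx;
}

// Matrix layout helpers: activations held as (H*W) x C matrices.
static fmat cube_to_mat(const fcube& x) {
  fmat m(x.n_rows * x.n_cols, x.n_slices);
  for (uword ch = 0; ch < x.n_slices; ++ch)
    m.col(ch) = vectorise(x.slice(ch));
  return m;
}
static fcube mat_to_cube(const fmat& m, uword H, uword W) {
  fcube x(H, W, m.n_cols);
  for (uword ch = 0; ch < m.n_cols; ++ch)
    x.slice(ch) = reshape(m.col(ch), H, W);
  return x;
}

// 2x2 max-pool, stride 2, floor semantics; records argmax linear indices.
static fcube maxpool2(const fcube& x, umat& idx) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  fcube out(Ho, Wo, C);
  idx.set_size(Ho * Wo, C);
  for (uword ch = 0; ch < C; ++ch) {
    const fmat& s = x.slice(ch);
    for (uword c = 0; c < Wo; ++c) {
      for (uword r = 0; r < Ho; ++r) {
        uword best = 2 * r + H * (2 * c);
        float bv = s(2 * r, 2 * c);
        const uword rr[4] = {2 * r, 2 * r + 1, 2 * r, 2 * r + 1};
        const uword cc[4] = {2 * c, 2 * c, 2 * c + 1, 2 * c + 1};
        for (int k = 1; k < 4; ++k) {
          const float v = s(rr[k], cc[k]);
          if (v > bv) { bv = v; best = rr[k] + H * cc[k]; }
        }
        out(r, c, ch) = bv;
        idx(r + Ho * c, ch) = best;
      }
    }
  }
  return out;
}

static fcube unpool2(const fcube& g, const umat& idx, uword H, uword W) {
  fcube out(H, W, g.n_slices, fill::zeros);
  for (uword ch = 0; ch < g.n_slices; ++ch) {
    const fvec gv = vectorise(g.slice(ch));
    for (uword p = 0; p < gv.n_elem; ++p)
      out.slice(ch)(idx(p, ch)) += gv(p);
  }
  return out;
}

// Bilinear resize weights (half-pixel-center convention, edges clamped).
struct LinMap { uvec i0, i1; fvec w1; };
static LinMap lin_map(uword n_out, uword n_in) {
  LinMap m;
  m.i0.set_size(n_out); m.i1.set_size(n_out); m.w1.set_size(n_out);
  const double scale = (double)n_in / (double)n_out;
  for (uword i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    const uword i0 = (uword)std::floor(s);
    const uword i1 = std::min(i0 + 1, n_in - 1);
    m.i0(i) = i0; m.i1(i) = i1; m.w1(i) = (float)(s - (double)i0);
  }
  return m;
}

static fcube bilinear_up(const fcube& x, uword H, uword W) {
  const LinMap mr = lin_map(H, x.n_rows), mc = lin_map(W, x.n_cols);
  fcube out(H, W, x.n_slices);
  for (uword ch = 0; ch < x.n_slices; ++ch) {
    const fmat& s = x.slice(ch);
    for (uword c = 0; c < W; ++c) {
      const uword c0 = mc.i0(c), c1 = mc.i1(c);
      const float wc = mc.w1(c);
      for (uword r = 0; r < H; ++r) {
        const uword r0 = mr.i0(r), r1 = mr.i1(r);
        const float wr = mr.w1(r);
        out(r, c, ch) =
          (1 - wr) * (1 - wc) * s(r0, c0) + wr * (1 - wc) * s(r1, c0) +
          (1 - wr) * wc * s(r0, c1) + wr * wc * s(r1, c1);
      }
    }
  }
  return out;
}

static fcube bilinear_down_adjoint(const fcube& g, uword h, uword w) {
  const LinMap mr = lin_map(g.n_rows, h), mc = lin_map(g.n_cols, w);
  fcube out(h, w, g.n_slices, fill::zeros);
  for (uword ch = 0; ch < g.n_slices; ++ch) {
    const fmat& s = g.slice(ch);
    fmat& o = out.slice(ch);
    for (uword c = 0; c < g.n_cols; ++c) {
      const uword c0 = mc.i0(c), c1 = mc.i1(c);
      const float wc = mc.w1(c);
      for (uword r = 0; r < g.n_rows; ++r) {
        const uword r0 = mr.i0(r), r1 = mr.i1(r);
        const float wr = mr.w1(r);
        const float v = s(r, c);
        o(r0, c0) += (1 - wr) * (1 - wc) * v;
        o(r1, c0) += wr * (1 - wc) * v;
        o(r0, c1) += (1 - wr) * wc * v;
        o(r1, c1) += wr * wc * v;
      }
    }
  }
  return out;
}

static fcube conv3_relu(const fcube& x, const fmat& Wm, const frowvec& b,
                        fmat* keepM = nullptr) {
  fmat M = im2col3(x);
  fmat Z = M * Wm;
  Z.each_row() += b;
  Z.clamp(0.0f, std::numeric_limits<float>::infinity());
  if (keepM) *keepM = std::move(M);
  return mat_to_cube(Z, x.n_rows, x.n_cols);
}

static fcube r_to_fcube(const Rcpp::NumericVector& x_) {
  Rcpp::IntegerVector dims = x_.attr("dim");
  fcube x(dims[0], dims[1], dims[2]);
  std::copy(x_.begin(), x_.end(), x.begin());
  return x;
}

struct FWeights {
  fmat W1, W2, W3, W4, W5;
  frowvec b1, b2, b3, b4, b5;
};

static FWeights get_weights(const List& weights) {
  FWeights w;
  w.W1 = conv_to<fmat>::from(Rcpp::as<mat>(weights["W1"]));
  w.W2 = conv_to<fmat>::from(Rcpp::as<mat>(weights["W2"]));
  w.W3 = conv_to<fmat>::from(Rcpp::as<mat>(weights["W3"]));
  w.W4 = conv_to<fmat>::from(Rcpp::as<mat>(weights["W4"]));
  w.W5 = conv_to<fmat>::from(Rcpp::as<mat>(weights["W5"]));
  w.b1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(weights["b1"]));
  w.b2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(weights["b2"]));
  w.b3 = conv_to<frowvec>::from(Rcpp::as<rowvec>(weights["b3"]));
  w.b4 = conv_to<frowvec>::from(Rcpp::as<rowvec>(weights["b4"]));
  w.b5 = conv_to<frowvec>::from(Rcpp::as<rowvec>(weights["b5"]));
  return w;
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::NumericVector x_, List weights) {
  Rcpp::IntegerVector dims = x_.attr("dim");
  fcube x = r_to_fcube(x_);
  FWeights w = get_weights(weights);
  umat i1, i2, i3;
  fcube a1 = conv3_relu(x, w.W1, w.b1);
  fcube p1 = maxpool2(a1, i1); a1.reset();
  fcube a2 = conv3_relu(p1, w.W2, w.b2); p1.reset();
  fcube p2 = maxpool2(a2, i2); a2.reset();
  fcube a3 = conv3_relu(p2, w.W3, w.b3); p2.reset();
  fcube p3 = maxpool2(a3, i3); a3.reset();
  fmat A4 = cube_to_mat(p3) * w.W4;
  A4.each_row() += w.b4;
  A4.clamp(0.0f, std::numeric_limits<float>::infinity());
  fmat S5 = A4 * w.W5;
  S5.each_row() += w.b5;
  S5.clamp(0.0f, std::numeric_limits<float>::infinity());
  fcube up = bilinear_up(mat_to_cube(S5, p3.n_rows, p3.n_cols),
                         dims[0], dims[1]);
  Rcpp::NumericVector out(up.n_elem);
  std::copy(up.begin(), up.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(dims[0], dims[1], 2);
  return out;
}

// Weighted softmax cross-entropy loss and parameter gradients for one frame.
// mask codes: 0 = unlabeled (weight 0), 1 = non-ablated (weight 1, class 0),
// 2 = ablated (weight w_abl, class 1). Loss = sum(w * ce) / sum(w).
// [[Rcpp::export(name = ".cnn_loss_grad_cpp")]]
List cnn_loss_grad_cpp(Rcpp::NumericVector x_, Rcpp::IntegerMatrix mask,
                       double w_abl, List weights, bool want_grads) {
  Rcpp::IntegerVector dims = x_.attr("dim");
  const uword H = dims[0], W = dims[1];
  fcube x = r_to_fcube(x_);
  FWeights w = get_weights(weights);

  umat i1, i2, i3;
  fmat M1, M2, M3;
  fcube a1 = conv3_relu(x, w.W1, w.b1, want_grads ? &M1 : nullptr);
  fcube p1 = maxpool2(a1, i1);
  fcube a2 = conv3_relu(p1, w.W2, w.b2, want_grads ? &M2 : nullptr);
  fcube p2 = maxpool2(a2, i2);
  fcube a3 = conv3_relu(p2, w.W3, w.b3, want_grads ? &M3 : nullptr);
  fcube p3 = maxpool2(a3, i3);
  const uword h3 = p3.n_rows, w3 = p3.n_cols;
  fmat P3 = cube_to_mat(p3);
  fmat Z4 = P3 * w.W4;
  Z4.each_row() += w.b4;
  fmat A4 = clamp(Z4, 0.0f, std::numeric_limits<float>::infinity());
  fmat Z5 = A4 * w.W5;
  Z5.each_row() += w.b5;
  fmat S5 = clamp(Z5, 0.0f, std::numeric_limits<float>::infinity());
  fcube up = bilinear_up(mat_to_cube(S5, h3, w3), H, W);

  // per-pixel weighted softmax CE on the two upsampled score channels
  // (accumulated in double for a stable loss value)
  double loss = 0.0, wsum = 0.0;
  fcube dup(H, W, 2, fill::zeros);
  for (uword c = 0; c < W; ++c) {
    for (uword r = 0; r < H; ++r) {
      const int code = mask(r, c);
      if (code == 0) continue;
      const double wt = (code == 2) ? w_abl : 1.0;
      const double s0 = up(r, c, 0), s1 = up(r, c, 1);
      const double m = std::max(s0, s1);
      const double z = std::exp(s0 - m) + std::exp(s1 - m);
      const double lp0 = s0 - m - std::log(z), lp1 = s1 - m - std::log(z);
      const double p0 = std::exp(lp0), p1 = std::exp(lp1);
      const int y = (code == 2) ? 1 : 0;
      loss += -wt * (y == 0 ? lp0 : lp1);
      wsum += wt;
      dup(r, c, 0) = (float)(wt * (p0 - (y == 0 ? 1.0 : 0.0)));
      dup(r, c, 1) = (float)(wt * (p1 - (y == 1 ? 1.0 : 0.0)));
    }
  }
  if (wsum > 0) loss /= wsum;

  if (!want_grads) return List::create(Named("loss") = loss,
                                       Named("weight_sum") = wsum);

  auto zmat = [](uword r, uword c) { return mat(r, c, fill::zeros); };
  if (wsum == 0) {
    List grads = List::create(
      Named("W1") = zmat(w.W1.n_rows, w.W1.n_cols),
      Named("b1") = rowvec(w.b1.n_elem, fill::zeros),
      Named("W2") = zmat(w.W2.n_rows, w.W2.n_cols),
      Named("b2") = rowvec(w.b2.n_elem, fill::zeros),
      Named("W3") = zmat(w.W3.n_rows, w.W3.n_cols),
      Named("b3") = rowvec(w.b3.n_elem, fill::zeros),
      Named("W4") = zmat(w.W4.n_rows, w.W4.n_cols),
      Named("b4") = rowvec(w.b4.n_elem, fill::zeros),
      Named("W5") = zmat(w.W5.n_rows, w.W5.n_cols),
      Named("b5") = rowvec(w.b5.n_elem, fill::zeros));
    return List::create(Named("loss") = loss, Named("weight_sum") = wsum,
                        Named("grads") = grads);
  }
  dup /= (float)wsum;

  fmat dS5 = cube_to_mat(bilinear_down_adjoint(dup, h3, w3));
  fmat dZ5 = dS5 % conv_to<fmat>::from(Z5 > 0);
  fmat dW5 = A4.t() * dZ5;
  frowvec db5 = sum(dZ5, 0);
  fmat dA4 = dZ5 * w.W5.t();
  fmat dZ4 = dA4 % conv_to<fmat>::from(Z4 > 0);
  fmat dW4 = P3.t() * dZ4;
  frowvec db4 = sum(dZ4, 0);
  fcube dp3 = mat_to_cube(dZ4 * w.W4.t(), h3, w3);

  fcube da3 = unpool2(dp3, i3, a3.n_rows, a3.n_cols);
  fmat dZ3 = cube_to_mat(da3);
  dZ3 %= conv_to<fmat>::from(cube_to_mat(a3) > 0);
  fmat dW3 = M3.t() * dZ3;
  frowvec db3 = sum(dZ3, 0);
  fcube dp2 = col2im3(dZ3 * w.W3.t(), p2.n_rows, p2.n_cols, p2.n_slices);

  fcube da2 = unpool2(dp2, i2, a2.n_rows, a2.n_cols);
  fmat dZ2 = cube_to_mat(da2);
  dZ2 %= conv_to<fmat>::from(cube_to_mat(a2) > 0);
  fmat dW2 = M2.t() * dZ2;
  frowvec db2 = sum(dZ2, 0);
  fcube dp1 = col2im3(dZ2 * w.W2.t(), p1.n_rows, p1.n_cols, p1.n_slices);

  fcube da1 = unpool2(dp1, i1, a1.n_rows, a1.n_cols);
  fmat dZ1 = cube_to_mat(da1);
  dZ1 %= conv_to<fmat>::from(cube_to_mat(a1) > 0);
  fmat dW1 = M1.t() * dZ1;
  frowvec db1 = sum(dZ1, 0);

  List grads = List::create(
    Named("W1") = conv_to<mat>::from(dW1),
    Named("b1") = conv_to<rowvec>::from(db1),
    Named("W2") = conv_to<mat>::from(dW2),
    Named("b2") = conv_to<rowvec>::from(db2),
    Named("W3") = conv_to<mat>::from(dW3),
    Named("b3") = conv_to<rowvec>::from(db3),
    Named("W4") = conv_to<mat>::from(dW4),
    Named("b4") = conv_to<rowvec>::from(db4),
    Named("W5") = conv_to<mat>::from(dW5),
    Named("b5") = conv_to<rowvec>::from(db5));
  return List::create(Named("loss") = loss, Named("weight_sum") = wsum,
                      Named("grads") = grads);
}
// ---------------------------------------------------------------------------
// k x k mean filter per channel with edge replication (separable box blur).
// ---------------------------------------------------------------------------
static vec box1d(const vec& v, int half) {
  const int n = v.n_elem;
  vec out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int d = -half; d <= half; ++d) {
      int j = i + d;
      if (j < 0) j = 0;
      if (j >= n) j = n - 1;
      s += v(j);
    }
    out(i) = s / (2 * half + 1);
  }
  return out;
}

// [[Rcpp::export(name = ".box_blur_cpp")]]
Rcpp::NumericVector box_blur_cpp(Rcpp::NumericVector x_, int k) {
  Rcpp::IntegerVector dims = x_.attr("dim");
  cube x(x_.begin(), dims[0], dims[1], dims[2]);
  const int half = (k - 1) / 2;
  cube out(size(x));
  for (uword ch = 0; ch < x.n_slices; ++ch) {
    mat s = x.slice(ch);
    for (uword c = 0; c < s.n_cols; ++c) s.col(c) = box1d(s.col(c), half);
    for (uword r = 0; r < s.n_rows; ++r)
      s.row(r) = box1d(s.row(r).t(), half).t();
    out.slice(ch) = s;
  }
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = dims;
  return res;
}

// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
arma::mat rbf_kernel_cpp(const arma::mat& X, const arma::mat& Y, double gamma) {
  const vec xs = sum(square(X), 1), ys = sum(square(Y), 1);
  mat D = repmat(xs, 1, Y.n_rows) + repmat(ys.t(), X.n_rows, 1) - 2.0 * X * Y.t();
  D.clamp(0.0, datum::inf);
  return exp(-gamma * D);
}

// ---------------------------------------------------------------------------
// Simplified SMO for the C-SVM dual on a precomputed kernel matrix.
// y in {-1, +1}. Keeps an error cache updated incrementally.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(const arma::mat& K, const arma::vec& y, double C,
                 double tol, int max_passes, int seed) {
  const uword n = y.n_elem;
  vec alpha(n, fill::zeros);
  vec f(n, fill::zeros);  // f_i = sum_j alpha_j y_j K_ij (no bias)
  double b = 0.0;
  std::mt19937 rng((unsigned)seed);
  int passes = 0, total_iter = 0;
  const int max_total = 200000;
  while (passes < max_passes && total_iter < max_total) {
    int changed = 0;
    for (uword i = 0; i < n; ++i) {
      ++total_iter;
      const double Ei = f(i) + b - y(i);
      if ((y(i) * Ei < -tol && alpha(i) < C) ||
          (y(i) * Ei > tol && alpha(i) > 0)) {
        uword j = rng() % (n - 1);
        if (j >= i) ++j;
        const double Ej = f(j) + b - y(j);
        const double ai_old = alpha(i), aj_old = alpha(j);
        double L, Hi;
        if (y(i) != y(j)) {
          L = std::max(0.0, aj_old - ai_old);
          Hi = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          Hi = std::min(C, ai_old + aj_old);
        }
        if (L >= Hi) continue;
        const double eta = 2 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0) continue;
        double aj = aj_old - y(j) * (Ei - Ej) / eta;
        aj = std::min(Hi, std::max(L, aj));
        if (std::abs(aj - aj_old) < 1e-7) continue;
        const double ai = ai_old + y(i) * y(j) * (aj_old - aj);
        alpha(i) = ai; alpha(j) = aj;
        f += (ai - ai_old) * y(i) * K.col(i) + (aj - aj_old) * y(j) * K.col(j);
        const double b1 = b - Ei - y(i) * (ai - ai_old) * K(i, i) -
                          y(j) * (aj - aj_old) * K(i, j);
        const double b2 = b - Ej - y(i) * (ai - ai_old) * K(i, j) -
                          y(j) * (aj - aj_old) * K(j, j);
        if (ai > 0 && ai < C) b = b1;
        else if (aj > 0 && aj < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(Named("alpha") = alpha, Named("b") = b,
                      Named("iterations") = total_iter);
}

// ---------------------------------------------------------------------------
// Random forest: bagged CART with gini impurity, per-split feature
// subsampling (mtry), and a minimum leaf size. Binary labels {0, 1}.
// Trees are flattened to a matrix: [feature, threshold, left, right, prob,
// depth]; feature == -1 marks a leaf.
// ---------------------------------------------------------------------------
struct TreeBuilder {
  const mat& X; const ivec& y;
  int mtry, min_leaf;
  std::mt19937& rng;
  std::vector<std::array<double, 6>> nodes;
  int max_depth = 0;

  TreeBuilder(const mat& X_, const ivec& y_, int mtry_, int min_leaf_,
              std::mt19937& rng_)
    : X(X_), y(y_), mtry(mtry_), min_leaf(min_leaf_), rng(rng_) {}

  int build(std::vector<uword>& idx, int depth) {
    if (depth > max_depth) max_depth = depth;
    const int node = (int)nodes.size();
    nodes.push_back({-1, 0, -1, -1, 0, (double)depth});
    int n1 = 0;
    for (uword i : idx) n1 += y(i);
    const int n = (int)idx.size();
    nodes[node][4] = (double)n1 / n;
    if (n1 == 0 || n1 == n || n < 2 * min_leaf) return node;

    // sample mtry features without replacement
    const int p = X.n_cols;
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feats[j], feats[u(rng)]);
    }
    double best_gain = 1e-12, best_thr = 0;
    int best_feat = -1;
    const double parent_imp = 2.0 * nodes[node][4] * (1.0 - nodes[node][4]);
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry && j < p; ++j) {
      const int feat = feats[j];
      for (int i = 0; i < n; ++i)
        vals[i] = {X(idx[i], feat), (int)y(idx[i])};
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (vals[i].first == vals[i + 1].first) continue;
        const double pl = (double)left1 / nl, pr = (double)(n1 - left1) / nr;
        const double imp = ((double)nl / n) * 2 * pl * (1 - pl) +
                           ((double)nr / n) * 2 * pr * (1 - pr);
        const double gain = parent_imp - imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = feat;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return node;
    std::vector<uword> li, ri;
    for (uword i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) return node;
    idx.clear(); idx.shrink_to_fit();
    nodes[node][0] = best_feat;
    nodes[node][1] = best_thr;
    const int l = build(li, depth + 1);
    nodes[node][2] = l;
    const int r = build(ri, depth + 1);
    nodes[node][3] = r;
    return node;
  }
};

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(const arma::mat& X, const arma::ivec& y, int n_trees,
                int mtry, int min_leaf, int seed) {
  std::mt19937 rng((unsigned)seed);
  const uword n = X.n_rows;
  List trees(n_trees);
  Rcpp::IntegerVector depths(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<uword> idx(n);
    std::uniform_int_distribution<uword> u(0, n - 1);
    for (uword i = 0; i < n; ++i) idx[i] = u(rng);
    TreeBuilder tb(X, y, mtry, min_leaf, rng);
    tb.build(idx, 0);
    mat nm(tb.nodes.size(), 6);
    for (uword i = 0; i < tb.nodes.size(); ++i)
      for (int j = 0; j < 6; ++j) nm(i, j) = tb.nodes[i][j];
    trees[t] = nm;
    depths[t] = tb.max_depth;
  }
  return List::create(Named("trees") = trees, Named("max_depths") = depths);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
arma::vec rf_predict_cpp(List trees, const arma::mat& X) {
  const uword n = X.n_rows;
  vec prob(n, fill::zeros);
  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    const mat nm = trees[t];
    for (uword i = 0; i < n; ++i) {
      int node = 0;
      while (nm(node, 0) >= 0) {
        const int feat = (int)nm(node, 0);
        node = (X(i, feat) <= nm(node, 1)) ? (int)nm(node, 2)
                                           : (int)nm(node, 3);
      }
      prob(i) += nm(node, 4);
    }
  }
  return prob / T;
}
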