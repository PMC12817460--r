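// Reference convolutional backbone: four 3x3 conv blocks (ReLU, 2x2 max
// pooling after the first three), global average pooling and a linear
// classifier. Small enough to train on one CPU; the global-average-pooled
// head is what makes class activation maps straightforward.
//
// Layout conventions: an image is an arma::cube (H x W x C); a batch is a
// Rcpp NumericMatrix n x (H*W) of single-channel inputs; conv weights are
// (9*Cin) x Cout matrices acting on im2col patches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube p(H + 2, W + 2, C, arma::fill::zeros);
  p.subcube(1, 1, 0, H, W, C - 1) = x;
  mat out(H * W, 9 * C);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy)
        out.col(col++) = arma::vectorise(p.slice(c).submat(dy, dx, dy + H - 1, dx + W - 1));
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube p(H + 2, W + 2, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy) {
        p.slice(c).submat(dy, dx, dy + H - 1, dx + W - 1) +=
          arma::reshape(cols.col(col++), H, W);
      }
  return p.subcube(1, 1, 0, H, W, C - 1);
}

struct LayerCache {
  cube input;       // layer input (pre-conv)
  mat z;            // pre-ReLU conv output, (H*W) x Cout
  arma::umat amax;  // pooling argmax (linear index into pre-pool map)
  bool pooled;
};

static cube conv_relu(const cube& x, const mat& W, const vec& b, LayerCache* cc) {
  const int H = x.n_rows, Wd = x.n_cols;
  mat A = im2col3(x);
  mat z = A * W;
  z.each_row() += b.t();
  if (cc) { cc->input = x; cc->z = z; }
  mat a = arma::clamp(z, 0.0, arma::datum::inf);
  cube out(H, Wd, W.n_cols);
  for (arma::uword c = 0; c < W.n_cols; ++c)
    out.slice(c) = arma::reshape(a.col(c), H, Wd);
  return out;
}

static cube maxpool2(const cube& x, arma::umat* amax) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  if (amax) amax->set_size(H * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            arma::uword idx = (2 * j + dj) * x.n_rows + (2 * i + di);
            double v = x.slice(c)(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = idx; }
          }
        out.slice(c)(i, j) = best;
        if (amax) (*amax)(j * H + i, c) = bi;
      }
  return out;
}

static cube forward_image(const List& weights, const vec& xrow, int H, int W,
                          std::vector<LayerCache>* caches) {
  cube x(H, W, 1);
  x.slice(0) = arma::reshape(mat(xrow), H, W);
  const int nlayer = 4;
  for (int l = 0; l < nlayer; ++l) {
    mat Wl = as<mat>(weights[2 * l]);
    vec bl = as<vec>(weights[2 * l + 1]);
    LayerCache cc;
    cc.pooled = (l < 3);
    cube a = conv_relu(x, Wl, bl, caches ? &cc : nullptr);
    if (l < 3) {
      arma::umat amax;
      x = maxpool2(a, caches ? &amax : nullptr);
      if (caches) cc.amax = amax;
    } else {
      x = a;
    }
    if (caches) caches->push_back(cc);
  }
  return x;  // final feature maps fh x fw x C4
}

// [[Rcpp::export(name = ".cnn_forward")]]
List cnn_forward(List weights, NumericMatrix x, int H, int W) {
  const int n = x.nrow();
  mat Wfc = as<mat>(weights["Wfc"]);
  vec bfc = as<vec>(weights["bfc"]);
  const int K = Wfc.n_cols;
  mat xm(x.begin(), n, x.ncol(), false);
  cube probe = forward_image(weights, xm.row(0).t(), H, W, nullptr);
  const int fh = probe.n_rows, fw = probe.n_cols, C4 = probe.n_slices;
  mat feat(n, fh * fw * C4), gap(n, C4), logits(n, K);
  for (int i = 0; i < n; ++i) {
    cube f = (i == 0) ? probe : forward_image(weights, xm.row(i).t(), H, W, nullptr);
    feat.row(i) = arma::vectorise(f).t();
    for (int c = 0; c < C4; ++c) gap(i, c) = arma::accu(f.slice(c)) / (fh * fw);
    logits.row(i) = gap.row(i) * Wfc + bfc.t();
  }
  return List::create(_["logits"] = logits, _["gap"] = gap, _["feat"] = feat,
                      _["feat_dim"] = IntegerVector::create(fh, fw, C4));
}

// One forward/backward pass over a batch. grad_fun(logits) must return the
// gradient of the (mean) loss with respect to the logits, n x K.
// [[Rcpp::export(name = ".cnn_step")]]
List cnn_step(List weights, NumericMatrix x, int H, int W, Function grad_fun) {
  const int n = x.nrow();
  mat Wfc = as<mat>(weights["Wfc"]);
  vec bfc = as<vec>(weights["bfc"]);
  const int K = Wfc.n_cols;
  mat xm(x.begin(), n, x.ncol(), false);

  std::vector<std::vector<LayerCache>> caches(n);
  std::vector<cube> feats(n);
  int fh = 0, fw = 0, C4 = 0;
  mat gap, logits(n, K);
  for (int i = 0; i < n; ++i) {
    feats[i] = forward_image(weights, xm.row(i).t(), H, W, &caches[i]);
    if (i == 0) {
      fh = feats[0].n_rows; fw = feats[0].n_cols; C4 = feats[0].n_slices;
      gap.set_size(n, C4);
    }
    for (int c = 0; c < C4; ++c)
      gap(i, c) = arma::accu(feats[i].slice(c)) / (fh * fw);
    logits.row(i) = gap.row(i) * Wfc + bfc.t();
  }

  mat dlogits = as<mat>(grad_fun(wrap(logits)));

  // fc gradients and gradient on the pooled features
  mat dWfc = gap.t() * dlogits;
  vec dbfc = arma::sum(dlogits, 0).t();
  mat dgap = dlogits * Wfc.t();

  // conv gradients, accumulated over the batch
  List grads(10);
  std::vector<mat> dW(4);
  std::vector<vec> db(4);
  for (int l = 0; l < 4; ++l) {
    mat Wl = as<mat>(weights[2 * l]);
    dW[l] = mat(Wl.n_rows, Wl.n_cols, arma::fill::zeros);
    db[l] = vec(Wl.n_cols, arma::fill::zeros);
  }
  for (int i = 0; i < n; ++i) {
    cube dx(fh, fw, C4);
    for (int c = 0; c < C4; ++c) dx.slice(c).fill(dgap(i, c) / (fh * fw));
    for (int l = 3; l >= 0; --l) {
      LayerCache& cc = caches[i][l];
      const int Hl = cc.input.n_rows, Wl_ = cc.input.n_cols;
      mat Wl = as<mat>(weights[2 * l]);
      mat dA;
      if (cc.pooled) {
        // route gradient through the pooling argmax
        const int ph = Hl / 2, pw = Wl_ / 2, C = dx.n_slices;
        mat dpre(Hl * Wl_, C, arma::fill::zeros);
        for (int c = 0; c < C; ++c) {
          for (int q = 0; q < ph * pw; ++q)
            dpre(cc.amax(q, c), c) += dx.slice(c)(q % ph, q / ph);
        }
        dA = dpre;
      } else {
        dA.set_size(Hl * Wl_, dx.n_slices);
        for (arma::uword c = 0; c < dx.n_slices; ++c)
          dA.col(c) = arma::vectorise(dx.slice(c));
      }
      mat dZ = dA % arma::conv_to<mat>::from(cc.z > 0);
      mat A = im2col3(cc.input);
      dW[l] += A.t() * dZ;
      db[l] += arma::sum(dZ, 0).t();
      if (l > 0) {
        mat dcols = dZ * Wl.t();
        dx = col2im3(dcols, Hl, Wl_, cc.input.n_slices);
      }
    }
  }
  for (int l = 0; l < 4; ++l) { grads[2 * l] = dW[l]; grads[2 * l + 1] = db[l]; }
  grads[8] = dWfc; grads[9] = dbfc;
  grads.attr("names") = CharacterVector::create(
    "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4", "Wfc", "bfc");
  return List::create(_["logits"] = logits, _["grads"] = grads);
}
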