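// Small patch-based convolutional pixel classifier, written against
// Armadillo.  Fixed topology: conv-conv-pool-conv-conv-pool-dense-dense
// with ReLU activations, max pooling 2x2/2, dropout on the hidden dense
// layer, softmax output, plain SGD with weight decay.  Filter counts,
// kernel size and dense width are configurable; all randomness (Xavier
// init, shuffling, dropout) comes from one std::mt19937 seed so training
// is bitwise reproducible on a given platform.
//
// Feature maps are arma::mat of shape (channels, h*w) with spatial index
// y + h*x; patches arrive as rows of an N x size^2 matrix (column-major
// within the patch frame, matching R's as.vector(matrix)).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Dims {
  int size, k, f1, f2, f3, f4, dh, nc;
  int s1, s2, p1, s3, s4, p2, flat;
};

static Dims make_dims(int size, int k, IntegerVector f, int dh, int nc) {
  Dims d;
  d.size = size; d.k = k;
  d.f1 = f[0]; d.f2 = f[1]; d.f3 = f[2]; d.f4 = f[3];
  d.dh = dh; d.nc = nc;
  d.s1 = size - k + 1;
  d.s2 = d.s1 - k + 1;
  d.p1 = d.s2 / 2;
  d.s3 = d.p1 - k + 1;
  d.s4 = d.s3 - k + 1;
  d.p2 = d.s4 / 2;
  d.flat = d.f4 * d.p2 * d.p2;
  if (d.s1 < 1 || d.s2 < 1 || d.p1 < 1 || d.s3 < 1 || d.s4 < 1 || d.p2 < 1)
    stop("patch size too small for this architecture");
  return d;
}

static arma::mat im2col(const arma::mat& map, int h, int w, int k) {
  const int C = map.n_rows, ho = h - k + 1, wo = w - k + 1;
  arma::mat col(C * k * k, ho * wo);
  for (int x = 0; x < wo; ++x)
    for (int y = 0; y < ho; ++y) {
      double* dst = col.colptr(y + ho * x);
      for (int kx = 0; kx < k; ++kx) {
        const double* src = map.colptr((y) + h * (x + kx));
        // rows of `map` are channels; copy k vertical neighbours
        for (int ky = 0; ky < k; ++ky)
          for (int c = 0; c < C; ++c)
            dst[c + C * (ky + k * kx)] = map(c, (y + ky) + h * (x + kx));
        (void)src;
      }
    }
  return col;
}

static void col2im(const arma::mat& dcol, arma::mat& dmap,
                   int h, int w, int k) {
  const int C = dmap.n_rows, ho = h - k + 1, wo = w - k + 1;
  dmap.zeros();
  for (int x = 0; x < wo; ++x)
    for (int y = 0; y < ho; ++y) {
      const double* src = dcol.colptr(y + ho * x);
      for (int kx = 0; kx < k; ++kx)
        for (int ky = 0; ky < k; ++ky)
          for (int c = 0; c < C; ++c)
            dmap(c, (y + ky) + h * (x + kx)) += src[c + C * (ky + k * kx)];
    }
}

// max-pool 2x2 stride 2 (floor); records argmax spatial index per output
static arma::mat pool2(const arma::mat& map, int h, int w,
                       arma::umat& argmax) {
  const int C = map.n_rows, ho = h / 2, wo = w / 2;
  arma::mat out(C, ho * wo);
  argmax.set_size(C, ho * wo);
  for (int x = 0; x < wo; ++x)
    for (int y = 0; y < ho; ++y) {
      const int o = y + ho * x;
      for (int c = 0; c < C; ++c) {
        double best = -1e300; int bi = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            const int i = (2 * y + dy) + h * (2 * x + dx);
            const double v = map(c, i);
            if (v > best) { best = v; bi = i; }
          }
        out(c, o) = best;
        argmax(c, o) = bi;
      }
    }
  return out;
}

struct Weights {
  arma::mat W1, W2, W3, W4, Wd, Wo;
  arma::vec b1, b2, b3, b4, bd, bo;
};

static Weights weights_from_list(const List& wl) {
  Weights w;
  w.W1 = as<arma::mat>(wl["W1"]); w.b1 = as<arma::vec>(wl["b1"]);
  w.W2 = as<arma::mat>(wl["W2"]); w.b2 = as<arma::vec>(wl["b2"]);
  w.W3 = as<arma::mat>(wl["W3"]); w.b3 = as<arma::vec>(wl["b3"]);
  w.W4 = as<arma::mat>(wl["W4"]); w.b4 = as<arma::vec>(wl["b4"]);
  w.Wd = as<arma::mat>(wl["Wd"]); w.bd = as<arma::vec>(wl["bd"]);
  w.Wo = as<arma::mat>(wl["Wo"]); w.bo = as<arma::vec>(wl["bo"]);
  return w;
}

static List weights_to_list(const Weights& w) {
  return List::create(
    _["W1"] = w.W1, _["b1"] = w.b1, _["W2"] = w.W2, _["b2"] = w.b2,
    _["W3"] = w.W3, _["b3"] = w.b3, _["W4"] = w.W4, _["b4"] = w.b4,
    _["Wd"] = w.Wd, _["bd"] = w.bd, _["Wo"] = w.Wo, _["bo"] = w.bo);
}

struct Cache {
  arma::mat in, col1, a1, col2, a2, pA, col3, a3, col4, a4, pB;
  arma::umat arg1, arg2;
  arma::vec flat, hpre, h, hdrop, logits, prob;
  arma::vec dropmask;
};

// forward pass for one patch (row of X); fills cache if train
static arma::vec forward_one(const double* xrow, const Dims& d,
                             const Weights& w, Cache& c, bool keep) {
  c.in = arma::mat(1, d.size * d.size);
  for (int i = 0; i < d.size * d.size; ++i) c.in(0, i) = xrow[i];

  c.col1 = im2col(c.in, d.size, d.size, d.k);
  c.a1 = w.W1 * c.col1;
  c.a1.each_col() += w.b1;
  c.a1.transform([](double v) { return v > 0 ? v : 0.0; });

  c.col2 = im2col(c.a1, d.s1, d.s1, d.k);
  c.a2 = w.W2 * c.col2;
  c.a2.each_col() += w.b2;
  c.a2.transform([](double v) { return v > 0 ? v : 0.0; });

  c.pA = pool2(c.a2, d.s2, d.s2, c.arg1);

  c.col3 = im2col(c.pA, d.p1, d.p1, d.k);
  c.a3 = w.W3 * c.col3;
  c.a3.each_col() += w.b3;
  c.a3.transform([](double v) { return v > 0 ? v : 0.0; });

  c.col4 = im2col(c.a3, d.s3, d.s3, d.k);
  c.a4 = w.W4 * c.col4;
  c.a4.each_col() += w.b4;
  c.a4.transform([](double v) { return v > 0 ? v : 0.0; });

  c.pB = pool2(c.a4, d.s4, d.s4, c.arg2);

  c.flat = arma::vectorise(c.pB);
  c.hpre = w.Wd * c.flat + w.bd;
  c.h = c.hpre;
  c.h.transform([](double v) { return v > 0 ? v : 0.0; });

  arma::vec hd = c.h;
  if (keep && c.dropmask.n_elem == c.h.n_elem) hd = c.h % c.dropmask;
  c.hdrop = hd;

  c.logits = w.Wo * hd + w.bo;
  const double mx = c.logits.max();
  arma::vec e = arma::exp(c.logits - mx);
  c.prob = e / arma::accu(e);
  return c.prob;
}

// backward for one patch; accumulates gradients into g
static void backward_one(const Dims& d, const Weights& w, const Cache& c,
                         int label, Weights& g) {
  arma::vec dlogit = c.prob;
  dlogit(label) -= 1.0;

  g.Wo += dlogit * c.hdrop.t();
  g.bo += dlogit;

  arma::vec dh = w.Wo.t() * dlogit;
  if (c.dropmask.n_elem == dh.n_elem) dh %= c.dropmask;
  for (arma::uword i = 0; i < dh.n_elem; ++i)
    if (c.hpre(i) <= 0) dh(i) = 0;

  g.Wd += dh * c.flat.t();
  g.bd += dh;

  arma::vec dflat = w.Wd.t() * dh;
  arma::mat dpB(d.f4, d.p2 * d.p2);
  std::memcpy(dpB.memptr(), dflat.memptr(), sizeof(double) * dflat.n_elem);

  // un-pool B
  arma::mat da4(d.f4, d.s4 * d.s4, arma::fill::zeros);
  for (arma::uword o = 0; o < dpB.n_cols; ++o)
    for (int ch = 0; ch < d.f4; ++ch)
      da4(ch, c.arg2(ch, o)) += dpB(ch, o);
  for (arma::uword i = 0; i < da4.n_elem; ++i)
    if (c.a4(i) <= 0) da4(i) = 0;

  g.W4 += da4 * c.col4.t();
  g.b4 += arma::sum(da4, 1);
  arma::mat dcol4 = w.W4.t() * da4;
  arma::mat da3(d.f3, d.s3 * d.s3);
  col2im(dcol4, da3, d.s3, d.s3, d.k);
  for (arma::uword i = 0; i < da3.n_elem; ++i)
    if (c.a3(i) <= 0) da3(i) = 0;

  g.W3 += da3 * c.col3.t();
  g.b3 += arma::sum(da3, 1);
  arma::mat dcol3 = w.W3.t() * da3;
  arma::mat dpA(d.f2, d.p1 * d.p1);
  col2im(dcol3, dpA, d.p1, d.p1, d.k);

  // un-pool A
  arma::mat da2(d.f2, d.s2 * d.s2, arma::fill::zeros);
  for (arma::uword o = 0; o < dpA.n_cols; ++o)
    for (int ch = 0; ch < d.f2; ++ch)
      da2(ch, c.arg1(ch, o)) += dpA(ch, o);
  for (arma::uword i = 0; i < da2.n_elem; ++i)
    if (c.a2(i) <= 0) da2(i) = 0;

  g.W2 += da2 * c.col2.t();
  g.b2 += arma::sum(da2, 1);
  arma::mat dcol2 = w.W2.t() * da2;
  arma::mat da1(d.f1, d.s1 * d.s1);
  col2im(dcol2, da1, d.s1, d.s1, d.k);
  for (arma::uword i = 0; i < da1.n_elem; ++i)
    if (c.a1(i) <= 0) da1(i) = 0;

  g.W1 += da1 * c.col1.t();
  g.b1 += arma::sum(da1, 1);
}

static arma::mat xavier(int rows, int cols, int fan_in, int fan_out,
                        std::mt19937& rng) {
  const double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> U(-lim, lim);
  arma::mat m(rows, cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = U(rng);
  return m;
}

// [[Rcpp::export]]
List cpp_cnn_init(int size, int k, IntegerVector filters, int dense,
                  int n_classes, int seed) {
  Dims d = make_dims(size, k, filters, dense, n_classes);
  std::mt19937 rng((unsigned)seed);
  Weights w;
  w.W1 = xavier(d.f1, k * k,        k * k,        d.f1 * k * k, rng);
  w.W2 = xavier(d.f2, k * k * d.f1, k * k * d.f1, d.f2 * k * k, rng);
  w.W3 = xavier(d.f3, k * k * d.f2, k * k * d.f2, d.f3 * k * k, rng);
  w.W4 = xavier(d.f4, k * k * d.f3, k * k * d.f3, d.f4 * k * k, rng);
  w.Wd = xavier(d.dh, d.flat, d.flat, d.dh, rng);
  w.Wo = xavier(d.nc, d.dh, d.dh, d.nc, rng);
  w.b1 = arma::vec(d.f1, arma::fill::zeros);
  w.b2 = arma::vec(d.f2, arma::fill::zeros);
  w.b3 = arma::vec(d.f3, arma::fill::zeros);
  w.b4 = arma::vec(d.f4, arma::fill::zeros);
  w.bd = arma::vec(d.dh, arma::fill::zeros);
  w.bo = arma::vec(d.nc, arma::fill::zeros);
  return weights_to_list(w);
}

static void zero_like(const Weights& w, Weights& g) {
  g.W1 = arma::mat(arma::size(w.W1), arma::fill::zeros);
  g.W2 = arma::mat(arma::size(w.W2), arma::fill::zeros);
  g.W3 = arma::mat(arma::size(w.W3), arma::fill::zeros);
  g.W4 = arma::mat(arma::size(w.W4), arma::fill::zeros);
  g.Wd = arma::mat(arma::size(w.Wd), arma::fill::zeros);
  g.Wo = arma::mat(arma::size(w.Wo), arma::fill::zeros);
  g.b1 = arma::vec(w.b1.n_elem, arma::fill::zeros);
  g.b2 = arma::vec(w.b2.n_elem, arma::fill::zeros);
  g.b3 = arma::vec(w.b3.n_elem, arma::fill::zeros);
  g.b4 = arma::vec(w.b4.n_elem, arma::fill::zeros);
  g.bd = arma::vec(w.bd.n_elem, arma::fill::zeros);
  g.bo = arma::vec(w.bo.n_elem, arma::fill::zeros);
}

static void sgd_step(arma::mat& W, const arma::mat& G, double lr, double wd,
                     double scale) {
  W -= lr * (G * scale + wd * W);
}
static void sgd_step(arma::vec& b, const arma::vec& G, double lr,
                     double scale) {
  b -= lr * (G * scale);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_forward(const NumericMatrix& X, const List& wl,
                              int size, int k, IntegerVector filters,
                              int dense, int n_classes) {
  Dims d = make_dims(size, k, filters, dense, n_classes);
  Weights w = weights_from_list(wl);
  const int n = X.nrow();
  NumericMatrix P(n, d.nc);
  Cache c;
  c.dropmask.reset();
  std::vector<double> row(d.size * d.size);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d.size * d.size; ++j) row[j] = X(i, j);
    arma::vec p = forward_one(row.data(), d, w, c, false);
    for (int j = 0; j < d.nc; ++j) P(i, j) = p(j);
  }
  return P;
}

// [[Rcpp::export]]
List cpp_cnn_train(const NumericMatrix& X, const IntegerVector& y,
                   const NumericMatrix& Xval, const IntegerVector& yval,
                   const List& wl, int size, int k, IntegerVector filters,
                   int dense, int n_classes, int epochs, double lr,
                   double lr_decay, double weight_decay, int batch,
                   double dropout, int seed) {
  Dims d = make_dims(size, k, filters, dense, n_classes);
  Weights w = weights_from_list(wl);
  const int n = X.nrow(), nv = Xval.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  std::vector<double> row(d.size * d.size);
  Cache c;

  // initial training loss before any update (determinism probe)
  double init_loss = 0.0;
  c.dropmask.reset();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d.size * d.size; ++j) row[j] = X(i, j);
    arma::vec p = forward_one(row.data(), d, w, c, false);
    init_loss += -std::log(std::max(p(y[i]), 1e-12));
  }
  init_loss /= std::max(n, 1);

  NumericVector ep_loss(epochs), ep_val(epochs);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  Weights g;
  double lr_ep = lr;
  for (int ep = 0; ep < epochs; ++ep) {
    if (ep > 0) lr_ep *= lr_decay;
    const double lr_now = lr_ep;
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch) {
      const int stop_ = std::min(n, start + batch);
      const int bs = stop_ - start;
      zero_like(w, g);
      for (int b = start; b < stop_; ++b) {
        const int i = idx[b];
        for (int j = 0; j < d.size * d.size; ++j) row[j] = X(i, j);
        if (dropout > 0) {
          c.dropmask.set_size(d.dh);
          for (int j = 0; j < d.dh; ++j)
            c.dropmask(j) = (U01(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        } else c.dropmask.reset();
        arma::vec p = forward_one(row.data(), d, w, c, true);
        loss += -std::log(std::max(p(y[i]), 1e-12));
        backward_one(d, w, c, y[i], g);
      }
      const double sc = 1.0 / bs;
      sgd_step(w.W1, g.W1, lr_now, weight_decay, sc); sgd_step(w.b1, g.b1, lr_now, sc);
      sgd_step(w.W2, g.W2, lr_now, weight_decay, sc); sgd_step(w.b2, g.b2, lr_now, sc);
      sgd_step(w.W3, g.W3, lr_now, weight_decay, sc); sgd_step(w.b3, g.b3, lr_now, sc);
      sgd_step(w.W4, g.W4, lr_now, weight_decay, sc); sgd_step(w.b4, g.b4, lr_now, sc);
      sgd_step(w.Wd, g.Wd, lr_now, weight_decay, sc); sgd_step(w.bd, g.bd, lr_now, sc);
      sgd_step(w.Wo, g.Wo, lr_now, weight_decay, sc); sgd_step(w.bo, g.bo, lr_now, sc);
      ++nb;
      if (nb % 20 == 0) Rcpp::checkUserInterrupt();
    }
    ep_loss[ep] = loss / std::max(n, 1);

    // validation accuracy
    int correct = 0;
    c.dropmask.reset();
    for (int i = 0; i < nv; ++i) {
      for (int j = 0; j < d.size * d.size; ++j) row[j] = Xval(i, j);
      arma::vec p = forward_one(row.data(), d, w, c, false);
      // first-in-order argmax tie break
      int best = 0;
      for (int j = 1; j < d.nc; ++j) if (p(j) > p(best)) best = j;
      if (best == yval[i]) ++correct;
    }
    ep_val[ep] = nv > 0 ? (double)correct / nv : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = weights_to_list(w),
                      _["initial_loss"] = init_loss,
                      _["train_loss"] = ep_loss,
                      _["val_accuracy"] = ep_val);
}

// Per-pixel sliding-window prediction over a whole stain image with
// reflection padding and per-position standardisation.  Returns an
// (H*W) x n_classes probability matrix, pixels in column-major order.
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict_image(const NumericMatrix& img,
                                    const NumericMatrix& mu,
                                    const NumericMatrix& sd,
                                    const List& wl, int size, int k,
                                    IntegerVector filters, int dense,
                                    int n_classes) {
  Dims d = make_dims(size, k, filters, dense, n_classes);
  Weights w = weights_from_list(wl);
  const int H = img.nrow(), W = img.ncol(), r = size / 2;
  NumericMatrix P(H * W, d.nc);
  Cache c;
  c.dropmask.reset();
  std::vector<double> row(size * size);
  // reflect index helper (no border repetition for n>1)
  auto refl = [](int i, int n) {
    if (n == 1) return 0;
    const int per = 2 * n;
    i = ((i % per) + per) % per;
    return i < n ? i : per - 1 - i;
  };
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int idx = 0;
      for (int dx = -r; dx <= r; ++dx) {
        const int xx = refl(x + dx, W);
        for (int dy = -r; dy <= r; ++dy) {
          const int yy = refl(y + dy, H);
          row[idx] = (img(yy, xx) - mu(dy + r, dx + r)) / sd(dy + r, dx + r);
          ++idx;
        }
      }
      arma::vec p = forward_one(row.data(), d, w, c, false);
      for (int j = 0; j < d.nc; ++j) P(y + H * x, j) = p(j);
    }
    if (x % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return P;
}
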