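// Mini-batch SGD with (Nesterov) momentum for the 9216-512-128-68 landmark
// regressor.  Training runs in single precision for throughput, matching the
// arithmetic of mainstream deep-learning frameworks; the package's R-level
// double-precision forward/backprop is the reference implementation the unit
// tests compare against.  Inputs are held transposed (features x samples) so
// mini-batch gathers are contiguous column copies.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define ANCHOR3D_HAVE_MXCSR 1
#endif
using namespace Rcpp;

// Flush denormal floats to zero for the duration of a training run (the
// standard deep-learning-framework setting): converged gradients otherwise
// drift into the denormal range and trigger the CPU's slow microcode path.
struct FlushDenormalsGuard {
#ifdef ANCHOR3D_HAVE_MXCSR
  unsigned int saved;
  FlushDenormalsGuard() : saved(_mm_getcsr()) {
    _mm_setcsr(saved | 0x8040u);  // FTZ | DAZ
  }
  ~FlushDenormalsGuard() { _mm_setcsr(saved); }
#endif
};

static arma::fmat as_fmat(const NumericMatrix &m) {
  arma::mat d(const_cast<double *>(m.begin()), m.nrow(), m.ncol(), false);
  return arma::conv_to<arma::fmat>::from(d);
}

static arma::frowvec as_frow(const NumericVector &v) {
  arma::rowvec d(const_cast<double *>(v.begin()), v.size(), false);
  return arma::conv_to<arma::frowvec>::from(d);
}

// Deterministic xorshift-based shuffle (independent of stdlib distributions
// so runs are reproducible across toolchains).
static void fy_shuffle(std::vector<arma::uword> &v, uint64_t &state) {
  for (size_t i = v.size(); i > 1; --i) {
    state ^= state << 13;
    state ^= state >> 7;
    state ^= state << 17;
    size_t j = (size_t)(state % i);
    std::swap(v[i - 1], v[j]);
  }
}

// Forward MSE given transposed inputs (features x samples).
static float mse_forward_t(const arma::fmat &Xt, const arma::fmat &Y,
                           const arma::fmat &W1, const arma::frowvec &b1,
                           const arma::fmat &W2, const arma::frowvec &b2,
                           const arma::fmat &W3, const arma::frowvec &b3) {
  arma::fmat H1 = Xt.t() * W1;
  H1.each_row() += b1;
  H1.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  arma::fmat H2 = H1 * W2;
  H2.each_row() += b2;
  H2.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  arma::fmat O = H2 * W3;
  O.each_row() += b3;
  return arma::accu(arma::square(O - Y)) / (float)(Y.n_rows * Y.n_cols);
}

// [[Rcpp::export(name = ".mlp_train_sgd")]]
List mlp_train_sgd(List params, NumericMatrix X, NumericMatrix Y,
                   IntegerVector train_idx, IntegerVector val_idx,
                   int epochs, int batch_size, double lr, double momentum,
                   bool nesterov, int seed) {
  FlushDenormalsGuard ftz;
  arma::fmat Xt = as_fmat(X).t();   // features x samples
  arma::fmat Yf = as_fmat(Y);
  arma::fmat W1 = as_fmat(params["W1"]), W2 = as_fmat(params["W2"]),
             W3 = as_fmat(params["W3"]);
  arma::frowvec b1 = as_frow(params["b1"]), b2 = as_frow(params["b2"]),
                b3 = as_frow(params["b3"]);
  arma::fmat vW1(arma::size(W1), arma::fill::zeros),
      vW2(arma::size(W2), arma::fill::zeros),
      vW3(arma::size(W3), arma::fill::zeros);
  arma::frowvec vb1(b1.n_elem, arma::fill::zeros),
      vb2(b2.n_elem, arma::fill::zeros), vb3(b3.n_elem, arma::fill::zeros);

  std::vector<arma::uword> tr(train_idx.size());
  for (int i = 0; i < train_idx.size(); ++i) tr[i] = (arma::uword)(train_idx[i] - 1);
  arma::uvec va(val_idx.size());
  for (int i = 0; i < val_idx.size(); ++i) va[i] = (arma::uword)(val_idx[i] - 1);
  arma::fmat Xval_t, Yval;
  if (va.n_elem > 0) {
    Xval_t = Xt.cols(va);
    Yval = Yf.rows(va);
  }

  const float flr = (float)lr, fmu = (float)momentum;
  uint64_t rng = (uint64_t)seed * 2654435761u + 1442695040888963407ull;
  NumericVector train_loss(epochs), val_loss(epochs);

  // Single fused pass per parameter block: v <- mu v - lr g, then the
  // Nesterov move theta += mu v - lr g (updated velocity) or the plain
  // momentum move theta += v.  Fusing halves the memory traffic of the
  // update, which dominates the per-batch cost at this layer size.
  auto update = [flr, fmu, nesterov](float *w, float *v, const float *g,
                                     size_t n) {
    if (nesterov) {
      for (size_t i = 0; i < n; ++i) {
        const float vi = fmu * v[i] - flr * g[i];
        v[i] = vi;
        w[i] += fmu * vi - flr * g[i];
      }
    } else {
      for (size_t i = 0; i < n; ++i) {
        const float vi = fmu * v[i] - flr * g[i];
        v[i] = vi;
        w[i] += vi;
      }
    }
  };

  // All per-batch work areas are allocated once and reused: per-batch
  // allocation of the W1-sized gradient block would otherwise dominate the
  // loop through page-fault churn.
  const arma::uword bs = (arma::uword)batch_size;
  arma::fmat Xb_t(Xt.n_rows, bs), Yb(bs, Yf.n_cols);
  arma::fmat A1(bs, W1.n_cols), H1(bs, W1.n_cols), dH1(bs, W1.n_cols);
  arma::fmat A2(bs, W2.n_cols), H2(bs, W2.n_cols), dH2(bs, W2.n_cols);
  arma::fmat O(bs, W3.n_cols), dO(bs, W3.n_cols);
  arma::fmat gW1(arma::size(W1)), gW2(arma::size(W2)), gW3(arma::size(W3));
  arma::frowvec gb1(b1.n_elem), gb2(b2.n_elem), gb3(b3.n_elem);

  for (int ep = 0; ep < epochs; ++ep) {
    fy_shuffle(tr, rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      size_t end = std::min(start + (size_t)batch_size, tr.size());
      const arma::uword nb = (arma::uword)(end - start);
      if (Xb_t.n_cols != nb) {
        Xb_t.set_size(Xt.n_rows, nb); Yb.set_size(nb, Yf.n_cols);
        A1.set_size(nb, W1.n_cols); H1.set_size(nb, W1.n_cols);
        dH1.set_size(nb, W1.n_cols);
        A2.set_size(nb, W2.n_cols); H2.set_size(nb, W2.n_cols);
        dH2.set_size(nb, W2.n_cols);
        O.set_size(nb, W3.n_cols); dO.set_size(nb, W3.n_cols);
      }
      for (size_t k = start; k < end; ++k) {
        Xb_t.col(k - start) = Xt.col(tr[k]);
        Yb.row(k - start) = Yf.row(tr[k]);
      }

      A1 = Xb_t.t() * W1;
      A1.each_row() += b1;
      H1 = arma::clamp(A1, 0.0f, std::numeric_limits<float>::max());
      A2 = H1 * W2;
      A2.each_row() += b2;
      H2 = arma::clamp(A2, 0.0f, std::numeric_limits<float>::max());
      O = H2 * W3;
      O.each_row() += b3;

      O -= Yb;                           // O now holds the residual
      const float loss = arma::accu(arma::square(O)) / (float)(O.n_rows * O.n_cols);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += loss;
      ++n_batches;

      dO = O * (2.0f / (float)(O.n_rows * O.n_cols));
      gW3 = H2.t() * dO;
      gb3 = arma::sum(dO, 0);
      dH2 = dO * W3.t();
      dH2.elem(arma::find(A2 <= 0.0f)).zeros();
      gW2 = H1.t() * dH2;
      gb2 = arma::sum(dH2, 0);
      dH1 = dH2 * W2.t();
      dH1.elem(arma::find(A1 <= 0.0f)).zeros();
      gW1 = Xb_t * dH1;
      gb1 = arma::sum(dH1, 0);

      update(W1.memptr(), vW1.memptr(), gW1.memptr(), W1.n_elem);
      update(W2.memptr(), vW2.memptr(), gW2.memptr(), W2.n_elem);
      update(W3.memptr(), vW3.memptr(), gW3.memptr(), W3.n_elem);
      update(b1.memptr(), vb1.memptr(), gb1.memptr(), b1.n_elem);
      update(b2.memptr(), vb2.memptr(), gb2.memptr(), b2.n_elem);
      update(b3.memptr(), vb3.memptr(), gb3.memptr(), b3.n_elem);
    }
    train_loss[ep] = ep_loss / std::max(n_batches, 1);
    val_loss[ep] = (va.n_elem > 0)
        ? mse_forward_t(Xval_t, Yval, W1, b1, W2, b2, W3, b3)
        : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["W1"] = wrap(arma::conv_to<arma::mat>::from(W1)),
      _["b1"] = wrap(arma::conv_to<arma::rowvec>::from(b1)),
      _["W2"] = wrap(arma::conv_to<arma::mat>::from(W2)),
      _["b2"] = wrap(arma::conv_to<arma::rowvec>::from(b2)),
      _["W3"] = wrap(arma::conv_to<arma::mat>::from(W3)),
      _["b3"] = wrap(arma::conv_to<arma::rowvec>::from(b3)),
      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}

// Single-precision forward pass over a matrix of normalized inputs, used for
// fast bulk prediction.
// [[Rcpp::export(name = ".mlp_forward_f32")]]
NumericMatrix mlp_forward_f32(List params, NumericMatrix X) {
  arma::fmat Xf = as_fmat(X);
  arma::fmat H1 = Xf * as_fmat(params["W1"]);
  H1.each_row() += as_frow(params["b1"]);
  H1 = arma::clamp(H1, 0.0f, std::numeric_limits<float>::max());
  arma::fmat H2 = H1 * as_fmat(params["W2"]);
  H2.each_row() += as_frow(params["b2"]);
  H2 = arma::clamp(H2, 0.0f, std::numeric_limits<float>::max());
  arma::fmat O = H2 * as_fmat(params["W3"]);
  O.each_row() += as_frow(params["b3"]);
  return wrap(arma::conv_to<arma::mat>::from(O));
}
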