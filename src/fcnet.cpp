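// Training core for the dense (fully connected) networks: mini-batch
// forward/backward passes and in-place Adam updates with preallocated
// buffers, so the per-batch memory footprint is constant regardless of
// dataset size. Arithmetic is single precision (the standard choice for
// stochastic-gradient training; parameters are returned as doubles), and
// all randomness (weight initialization, shuffling order) is drawn in R
// and passed in, keeping runs reproducible from R's seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace arma;

// Flush subnormal floats to zero for this thread: saturated sigmoids and
// decayed pulse tails otherwise produce denormals whose arithmetic is
// pathologically slow.
static void enable_ftz() {
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

// activation codes: 0 = linear, 1 = relu, 2 = sigmoid
static void apply_act(fmat& z, int act) {
  if (act == 1) {
    z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  } else if (act == 2) {
    // logits clamped to +/-30: keeps saturated outputs well away from the
    // subnormal range while leaving the usable range untouched
    z.transform([](float v) {
      v = std::max(-30.0f, std::min(30.0f, v));
      return 1.0f / (1.0f + std::exp(-v));
    });
  }
}

// multiply delta (in place) by the activation derivative, given the
// activation output h
static void act_deriv(fmat& delta, const fmat& h, int act) {
  if (act == 1) {
    delta %= conv_to<fmat>::from(h > 0.0f);
  } else if (act == 2) {
    delta %= h % (1.0f - h);
  }
}

// [[Rcpp::export]]
Rcpp::List fc_fit_core(const arma::mat& x, const arma::mat& y,
                       Rcpp::List w0, Rcpp::List b0,
                       const arma::ivec& acts, int loss_code,
                       int epochs, int batch,
                       const arma::vec& lr_per_epoch,
                       const arma::imat& perms,
                       double beta1, double beta2, double eps,
                       int verbose = 0) {
  enable_ftz();
  const int nl = w0.size();
  const fmat xf = conv_to<fmat>::from(x);
  const fmat yf = conv_to<fmat>::from(y);
  std::vector<fmat> w(nl), mw(nl), vw(nl), gw(nl);
  std::vector<frowvec> b(nl), mb(nl), vb(nl), gb(nl);
  for (int l = 0; l < nl; ++l) {
    w[l] = conv_to<fmat>::from(Rcpp::as<mat>(w0[l]));
    b[l] = conv_to<frowvec>::from(Rcpp::as<rowvec>(b0[l]));
    mw[l] = zeros<fmat>(size(w[l]));
    vw[l] = zeros<fmat>(size(w[l]));
    gw[l] = zeros<fmat>(size(w[l]));
    mb[l] = zeros<frowvec>(size(b[l]));
    vb[l] = zeros<frowvec>(size(b[l]));
    gb[l] = zeros<frowvec>(size(b[l]));
  }
  const uword n = xf.n_rows;
  vec history(epochs, fill::zeros);
  std::vector<fmat> h(nl + 1);
  long t_step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    const float lr = static_cast<float>(lr_per_epoch(ep));
    double ep_loss = 0.0;
    int n_batch = 0;
    for (uword s = 0; s < n; s += batch) {
      const uword e = std::min<uword>(s + batch, n) - 1;
      uvec idx(e - s + 1);
      for (uword i = s; i <= e; ++i) {
        idx(i - s) = static_cast<uword>(perms(i, ep));
      }
      // forward
      h[0] = xf.rows(idx);
      for (int l = 0; l < nl; ++l) {
        h[l + 1] = h[l] * w[l];
        h[l + 1].each_row() += b[l];
        apply_act(h[l + 1], acts(l));
      }
      // loss and output delta
      fmat delta;
      double batch_loss;
      const fmat yb = yf.rows(idx);
      if (loss_code == 0) { // mse
        delta = h[nl] - yb;
        batch_loss = accu(conv_to<mat>::from(square(delta))) / delta.n_elem;
        delta *= 2.0f / static_cast<float>(delta.n_elem);
        act_deriv(delta, h[nl], acts(nl - 1));
      } else { // softmax cross-entropy on logits
        const fvec mx = max(h[nl], 1);
        fmat p = h[nl];
        p.each_col() -= mx;
        p = exp(p);
        const fvec rs = sum(p, 1);
        p.each_col() /= rs;
        // mean over rows of (log-sum-exp - true-class logit)
        batch_loss = (accu(log(rs)) + accu(mx) - accu(yb % h[nl])) /
          static_cast<double>(h[nl].n_rows);
        delta = (p - yb) / static_cast<float>(h[nl].n_rows);
      }
      if (!std::isfinite(batch_loss)) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      }
      // backward
      for (int l = nl - 1; l >= 0; --l) {
        gw[l] = h[l].t() * delta;
        gb[l] = sum(delta, 0);
        if (l > 0) {
          delta = delta * w[l].t();
          act_deriv(delta, h[l], acts(l - 1));
        }
      }
      // in-place Adam
      ++t_step;
      const float bc1 = 1.0f - std::pow(static_cast<float>(beta1), t_step);
      const float bc2 = 1.0f - std::pow(static_cast<float>(beta2), t_step);
      const float b1 = static_cast<float>(beta1);
      const float b2 = static_cast<float>(beta2);
      const float epsf = static_cast<float>(eps);
      for (int l = 0; l < nl; ++l) {
        float* wp = w[l].memptr();
        float* mp = mw[l].memptr();
        float* vp = vw[l].memptr();
        const float* gp = gw[l].memptr();
        const uword ne = w[l].n_elem;
        for (uword i = 0; i < ne; ++i) {
          const float g = gp[i];
          const float m = mp[i] = b1 * mp[i] + (1.0f - b1) * g;
          const float v = vp[i] = b2 * vp[i] + (1.0f - b2) * g * g;
          wp[i] -= lr * (m / bc1) / (std::sqrt(v / bc2) + epsf);
        }
        float* bp = b[l].memptr();
        float* mbp = mb[l].memptr();
        float* vbp = vb[l].memptr();
        const float* gbp = gb[l].memptr();
        for (uword i = 0; i < b[l].n_elem; ++i) {
          const float g = gbp[i];
          const float m = mbp[i] = b1 * mbp[i] + (1.0f - b1) * g;
          const float v = vbp[i] = b2 * vbp[i] + (1.0f - b2) * g * g;
          bp[i] -= lr * (m / bc1) / (std::sqrt(v / bc2) + epsf);
        }
      }
      ep_loss += batch_loss;
      ++n_batch;
    }
    history(ep) = ep_loss / n_batch;
    if (verbose) {
      Rcpp::Rcout << "epoch " << ep + 1 << " loss " << history(ep)
                  << " at " << clock() / CLOCKS_PER_SEC << " s cpu"
                  << std::endl;
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List w_out(nl), b_out(nl);
  for (int l = 0; l < nl; ++l) {
    w_out[l] = conv_to<mat>::from(w[l]);
    rowvec bd = conv_to<rowvec>::from(b[l]);
    b_out[l] = Rcpp::NumericVector(bd.begin(), bd.end());
  }
  return Rcpp::List::create(Rcpp::Named("w") = w_out,
                            Rcpp::Named("b") = b_out,
                            Rcpp::Named("history") = history);
}

// Batched forward pass mirroring the training arithmetic (single
// precision), for bulk prediction.
// [[Rcpp::export]]
arma::mat fc_predict_core(const arma::mat& x, Rcpp::List w0, Rcpp::List b0,
                          const arma::ivec& acts) {
  enable_ftz();
  const int nl = w0.size();
  fmat h = conv_to<fmat>::from(x);
  for (int l = 0; l < nl; ++l) {
    const fmat w = conv_to<fmat>::from(Rcpp::as<mat>(w0[l]));
    const frowvec b = conv_to<frowvec>::from(Rcpp::as<rowvec>(b0[l]));
    h = h * w;
    h.each_row() += b;
    apply_act(h, acts(l));
  }
  return conv_to<mat>::from(h);
}
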