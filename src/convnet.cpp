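// Training core for the convolutional encoder-decoder ("U-Net") on the
// 64x64 waveform reshape. Same engineering pattern as fcnet.cpp: single
// precision, im2col + GEMM convolutions, in-place Adam, preallocated
// index tables, all randomness drawn in R. Activations are stored as
// (batch x H*W*C) matrices with channel-plane layout (column c*H*W + p,
// pixels column-major), matching the pure-R reference implementation,
// which serves as the correctness oracle in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace arma;

static void enable_ftz_cn() {
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

namespace {

constexpr uword PAD = std::numeric_limits<uword>::max();

// 3x3 same-padding tap table: for each output pixel p (column-major) and
// tap t (dy-major, matching the R reference), the source pixel index or PAD
uvec make_taps(uword h, uword w) {
  uvec taps(h * w * 9);
  for (uword x = 0; x < w; ++x) {
    for (uword y = 0; y < h; ++y) {
      const uword p = x * h + y;
      uword t = 0;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++t) {
          const long sy = static_cast<long>(y) + dy;
          const long sx = static_cast<long>(x) + dx;
          taps(p * 9 + t) =
            (sy < 0 || sy >= static_cast<long>(h) || sx < 0 ||
             sx >= static_cast<long>(w))
              ? PAD
              : static_cast<uword>(sx) * h + static_cast<uword>(sy);
        }
      }
    }
  }
  return taps;
}

// x: (B x H*W*Cin) -> col: (B*H*W x 9*Cin), row index b + B*p
void im2col(const fmat& x, uword h, uword w, uword cin, const uvec& taps,
            fmat& col) {
  const uword b = x.n_rows, hw = h * w;
  col.set_size(b * hw, 9 * cin);
  for (uword c = 0; c < cin; ++c) {
    const float* xc = x.colptr(c * hw);
    for (uword t = 0; t < 9; ++t) {
      float* dst = col.colptr(t * cin + c);
      for (uword p = 0; p < hw; ++p) {
        const uword src = taps(p * 9 + t);
        if (src == PAD) {
          std::memset(dst + b * p, 0, b * sizeof(float));
        } else {
          std::memcpy(dst + b * p, xc + b * src, b * sizeof(float));
        }
      }
    }
  }
}

// transpose of im2col: scatter-add dcol back onto dx (B x H*W*Cin)
void col2im(const fmat& dcol, uword h, uword w, uword cin, const uvec& taps,
            fmat& dx) {
  const uword hw = h * w;
  const uword b = dcol.n_rows / hw;
  dx.zeros(b, hw * cin);
  for (uword c = 0; c < cin; ++c) {
    float* xc = dx.colptr(c * hw);
    for (uword t = 0; t < 9; ++t) {
      const float* src = dcol.colptr(t * cin + c);
      for (uword p = 0; p < hw; ++p) {
        const uword dst = taps(p * 9 + t);
        if (dst == PAD) continue;
        float* out = xc + b * dst;
        const float* in = src + b * p;
        for (uword i = 0; i < b; ++i) out[i] += in[i];
      }
    }
  }
}

// y (B*H*W x Cout) -> out (B x H*W*Cout); columns line up exactly
void degroup(const fmat& y, uword b, uword hw, fmat& out) {
  out.set_size(b, hw * y.n_cols);
  for (uword co = 0; co < y.n_cols; ++co) {
    std::memcpy(out.colptr(co * hw), y.colptr(co), b * hw * sizeof(float));
  }
}

void regroup(const fmat& dout, uword b, uword hw, uword cout, fmat& dy) {
  dy.set_size(b * hw, cout);
  for (uword co = 0; co < cout; ++co) {
    std::memcpy(dy.colptr(co), dout.colptr(co * hw),
                b * hw * sizeof(float));
  }
}

struct ConvLayer {
  fmat w, mw, vw, gw;
  frowvec b, mb, vb, gb;
  uword cin = 0, cout = 0;
};

// conv3x3 + optional relu; keeps the im2col buffer for the backward pass
void conv_forward(const fmat& x, uword h, uword w, ConvLayer& ly,
                  const uvec& taps, bool relu, fmat& col, fmat& out) {
  im2col(x, h, w, ly.cin, taps, col);
  fmat y = col * ly.w;
  y.each_row() += ly.b;
  if (relu) y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  degroup(y, x.n_rows, h * w, out);
}

// relu derivative applied via the stored activation `act`
void conv_backward(const fmat& dact, const fmat& act, bool relu,
                   const fmat& col, uword h, uword w, ConvLayer& ly,
                   const uvec& taps, fmat& dx, bool want_dx) {
  fmat dout = dact;
  if (relu) {
    const float* a = act.memptr();
    float* d = dout.memptr();
    for (uword i = 0; i < dout.n_elem; ++i) {
      if (a[i] <= 0.0f) d[i] = 0.0f;
    }
  }
  const uword b = dact.n_rows, hw = h * w;
  fmat dy;
  regroup(dout, b, hw, ly.cout, dy);
  ly.gw = col.t() * dy;
  ly.gb = sum(dy, 0);
  if (want_dx) {
    fmat dcol = dy * ly.w.t();
    col2im(dcol, h, w, ly.cin, taps, dx);
  }
}

// 2x2 max pool, channel-plane layout; records argmax source pixels
void pool_forward(const fmat& x, uword h, uword w, uword c, fmat& out,
                  umat& amax) {
  const uword b = x.n_rows, h2 = h / 2, w2 = w / 2;
  out.set_size(b, h2 * w2 * c);
  amax.set_size(b, h2 * w2 * c);
  for (uword ch = 0; ch < c; ++ch) {
    for (uword x2 = 0; x2 < w2; ++x2) {
      for (uword y2 = 0; y2 < h2; ++y2) {
        const uword po = ch * h2 * w2 + x2 * h2 + y2;
        const uword s[4] = {
          ch * h * w + (2 * x2) * h + 2 * y2,
          ch * h * w + (2 * x2) * h + 2 * y2 + 1,
          ch * h * w + (2 * x2 + 1) * h + 2 * y2,
          ch * h * w + (2 * x2 + 1) * h + 2 * y2 + 1};
        for (uword i = 0; i < b; ++i) {
          float best = x(i, s[0]);
          uword bi = s[0];
          for (int k = 1; k < 4; ++k) {
            const float v = x(i, s[k]);
            if (v > best) { best = v; bi = s[k]; }
          }
          out(i, po) = best;
          amax(i, po) = bi;
        }
      }
    }
  }
}

void pool_backward(const fmat& dout, const umat& amax, uword h, uword w,
                   uword c, fmat& dx) {
  dx.zeros(dout.n_rows, h * w * c);
  for (uword j = 0; j < dout.n_cols; ++j) {
    for (uword i = 0; i < dout.n_rows; ++i) {
      dx(i, amax(i, j)) += dout(i, j);
    }
  }
}

// nearest-neighbour 2x upsample
void up_forward(const fmat& x, uword h, uword w, uword c, fmat& out) {
  const uword b = x.n_rows, h2 = 2 * h, w2 = 2 * w;
  out.set_size(b, h2 * w2 * c);
  for (uword ch = 0; ch < c; ++ch) {
    for (uword x2 = 0; x2 < w2; ++x2) {
      for (uword y2 = 0; y2 < h2; ++y2) {
        const uword src = ch * h * w + (x2 / 2) * h + y2 / 2;
        out.col(ch * h2 * w2 + x2 * h2 + y2) = x.col(src);
      }
    }
  }
}

void up_backward(const fmat& dout, uword h, uword w, uword c, fmat& dx) {
  const uword h2 = 2 * h, w2 = 2 * w;
  dx.zeros(dout.n_rows, h * w * c);
  for (uword ch = 0; ch < c; ++ch) {
    for (uword x2 = 0; x2 < w2; ++x2) {
      for (uword y2 = 0; y2 < h2; ++y2) {
        dx.col(ch * h * w + (x2 / 2) * h + y2 / 2) +=
          dout.col(ch * h2 * w2 + x2 * h2 + y2);
      }
    }
  }
}

void adam_update(ConvLayer& ly, float lr, float b1, float b2, float bc1,
                 float bc2, float eps) {
  float* wp = ly.w.memptr();
  float* mp = ly.mw.memptr();
  float* vp = ly.vw.memptr();
  const float* gp = ly.gw.memptr();
  for (uword i = 0; i < ly.w.n_elem; ++i) {
    const float g = gp[i];
    const float m = mp[i] = b1 * mp[i] + (1.0f - b1) * g;
    const float v = vp[i] = b2 * vp[i] + (1.0f - b2) * g * g;
    wp[i] -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
  }
  float* bp = ly.b.memptr();
  float* mbp = ly.mb.memptr();
  float* vbp = ly.vb.memptr();
  const float* gbp = ly.gb.memptr();
  for (uword i = 0; i < ly.b.n_elem; ++i) {
    const float g = gbp[i];
    const float m = mbp[i] = b1 * mbp[i] + (1.0f - b1) * g;
    const float v = vbp[i] = b2 * vbp[i] + (1.0f - b2) * g * g;
    bp[i] -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
  }
}

struct UNet {
  // layer order: e1 e2 e3 bn d3 d2 d1 out(1x1)
  std::vector<ConvLayer> ly;
  uword base = 8, side = 64;
};

struct Cache {
  fmat a1, a2, a3, ab, b3, b2, b1, out;    // activations
  fmat c1, c2, c3, cb, cd3, cd2, cd1;      // im2col buffers
  fmat p1, p2, p3, u3, u2, u1;             // pooled / concat inputs
  umat m1, m2, m3;                         // pool argmax
};

void unet_forward_core(const UNet& net, const fmat& x, Cache& K,
                       bool keep) {
  const uword s = net.side, c1n = net.base, c2n = 2 * net.base,
              c3n = 4 * net.base, cbn = 8 * net.base;
  const uvec t64 = make_taps(s, s), t32 = make_taps(s / 2, s / 2),
             t16 = make_taps(s / 4, s / 4), t8 = make_taps(s / 8, s / 8);
  auto& L = const_cast<std::vector<ConvLayer>&>(net.ly);
  conv_forward(x, s, s, L[0], t64, true, K.c1, K.a1);
  pool_forward(K.a1, s, s, c1n, K.p1, K.m1);
  conv_forward(K.p1, s / 2, s / 2, L[1], t32, true, K.c2, K.a2);
  pool_forward(K.a2, s / 2, s / 2, c2n, K.p2, K.m2);
  conv_forward(K.p2, s / 4, s / 4, L[2], t16, true, K.c3, K.a3);
  pool_forward(K.a3, s / 4, s / 4, c3n, K.p3, K.m3);
  conv_forward(K.p3, s / 8, s / 8, L[3], t8, true, K.cb, K.ab);
  fmat up;
  up_forward(K.ab, s / 8, s / 8, cbn, up);
  K.u3 = join_rows(up, K.a3);
  conv_forward(K.u3, s / 4, s / 4, L[4], t16, true, K.cd3, K.b3);
  up_forward(K.b3, s / 4, s / 4, c3n, up);
  K.u2 = join_rows(up, K.a2);
  conv_forward(K.u2, s / 2, s / 2, L[5], t32, true, K.cd2, K.b2);
  up_forward(K.b2, s / 2, s / 2, c2n, up);
  K.u1 = join_rows(up, K.a1);
  conv_forward(K.u1, s, s, L[6], t64, true, K.cd1, K.b1);
  // 1x1 sigmoid head over channels
  const uword hw = s * s, b = x.n_rows;
  K.out.zeros(b, hw);
  for (uword c = 0; c < c1n; ++c) {
    K.out += K.b1.cols(c * hw, (c + 1) * hw - 1) * net.ly[7].w(c, 0);
  }
  K.out += net.ly[7].b(0);
  K.out.transform([](float v) {
    v = std::max(-30.0f, std::min(30.0f, v));
    return 1.0f / (1.0f + std::exp(-v));
  });
  (void)keep;
}

double unet_backward_core(UNet& net, const fmat& x, const fmat& y,
                          Cache& K) {
  const uword s = net.side, c1n = net.base, c2n = 2 * net.base,
              c3n = 4 * net.base, cbn = 8 * net.base;
  const uword hw = s * s, b = x.n_rows;
  const uvec t64 = make_taps(s, s), t32 = make_taps(s / 2, s / 2),
             t16 = make_taps(s / 4, s / 4), t8 = make_taps(s / 8, s / 8);
  fmat diff = K.out - y;
  const double loss = accu(conv_to<mat>::from(square(diff))) / diff.n_elem;
  // MSE through sigmoid
  fmat dz = (2.0f / static_cast<float>(diff.n_elem)) * diff %
    K.out % (1.0f - K.out);
  // 1x1 head gradients
  auto& L = net.ly;
  L[7].gw.set_size(c1n, 1);
  for (uword c = 0; c < c1n; ++c) {
    L[7].gw(c, 0) =
      accu(dz % K.b1.cols(c * hw, (c + 1) * hw - 1));
  }
  L[7].gb.set_size(1);
  L[7].gb(0) = accu(dz);
  fmat db1(b, hw * c1n);
  for (uword c = 0; c < c1n; ++c) {
    db1.cols(c * hw, (c + 1) * hw - 1) = dz * L[7].w(c, 0);
  }
  fmat du1, dup, dskip, dtmp;
  conv_backward(db1, K.b1, true, K.cd1, s, s, L[6], t64, du1, true);
  // split concat: first 2*base channels came from up(b2), rest from a1
  fmat da1 = du1.cols(c2n * hw, du1.n_cols - 1);
  up_backward(du1.cols(0, c2n * hw - 1), s / 2, s / 2, c2n, dtmp);
  conv_backward(dtmp, K.b2, true, K.cd2, s / 2, s / 2, L[5], t32, du1,
                true);
  const uword hw2 = hw / 4;
  fmat da2 = du1.cols(c3n * hw2, du1.n_cols - 1);
  up_backward(du1.cols(0, c3n * hw2 - 1), s / 4, s / 4, c3n, dtmp);
  conv_backward(dtmp, K.b3, true, K.cd3, s / 4, s / 4, L[4], t16, du1,
                true);
  const uword hw4 = hw / 16;
  fmat da3 = du1.cols(cbn * hw4, du1.n_cols - 1);
  up_backward(du1.cols(0, cbn * hw4 - 1), s / 8, s / 8, cbn, dtmp);
  conv_backward(dtmp, K.ab, true, K.cb, s / 8, s / 8, L[3], t8, du1, true);
  pool_backward(du1, K.m3, s / 4, s / 4, c3n, dtmp);
  da3 += dtmp;
  conv_backward(da3, K.a3, true, K.c3, s / 4, s / 4, L[2], t16, du1, true);
  pool_backward(du1, K.m2, s / 2, s / 2, c2n, dtmp);
  da2 += dtmp;
  conv_backward(da2, K.a2, true, K.c2, s / 2, s / 2, L[1], t32, du1, true);
  pool_backward(du1, K.m1, s, s, c1n, dtmp);
  da1 += dtmp;
  conv_backward(da1, K.a1, true, K.c1, s, s, L[0], t64, du1, false);
  return loss;
}

UNet build_net(Rcpp::List w0, Rcpp::List b0, int base, int side) {
  UNet net;
  net.base = base;
  net.side = side;
  net.ly.resize(8);
  for (int l = 0; l < 8; ++l) {
    net.ly[l].w = conv_to<fmat>::from(Rcpp::as<mat>(w0[l]));
    net.ly[l].b =
      conv_to<frowvec>::from(Rcpp::as<rowvec>(b0[l]));
    net.ly[l].cout = net.ly[l].w.n_cols;
    net.ly[l].cin =
      (l == 7) ? net.ly[l].w.n_rows : net.ly[l].w.n_rows / 9;
    net.ly[l].mw = zeros<fmat>(size(net.ly[l].w));
    net.ly[l].vw = zeros<fmat>(size(net.ly[l].w));
    net.ly[l].mb = zeros<frowvec>(size(net.ly[l].b));
    net.ly[l].vb = zeros<frowvec>(size(net.ly[l].b));
  }
  return net;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List unet_fit_core(const arma::mat& x, const arma::mat& y,
                         Rcpp::List w0, Rcpp::List b0, int base, int side,
                         int epochs, int batch,
                         const arma::vec& lr_per_epoch,
                         const arma::imat& perms, double beta1,
                         double beta2, double eps, int verbose = 0) {
  enable_ftz_cn();
  UNet net = build_net(w0, b0, base, side);
  const fmat xf = conv_to<fmat>::from(x);
  const fmat yf = conv_to<fmat>::from(y);
  const uword n = xf.n_rows;
  vec history(epochs, fill::zeros);
  Cache K;
  long t_step = 0;
  const float b1 = beta1, b2 = beta2, ef = eps;
  for (int ep = 0; ep < epochs; ++ep) {
    const float lr = static_cast<float>(lr_per_epoch(ep));
    double ep_loss = 0.0;
    int n_batch = 0;
    for (uword s0 = 0; s0 < n; s0 += batch) {
      const uword e = std::min<uword>(s0 + batch, n) - 1;
      uvec idx(e - s0 + 1);
      for (uword i = s0; i <= e; ++i) {
        idx(i - s0) = static_cast<uword>(perms(i, ep));
      }
      const fmat xb = xf.rows(idx);
      const fmat yb = yf.rows(idx);
      unet_forward_core(net, xb, K, true);
      const double loss = unet_backward_core(net, xb, yb, K);
      if (!std::isfinite(loss)) {
        Rcpp::stop("U-Net training diverged (non-finite loss)");
      }
      ++t_step;
      const float bc1 = 1.0f - std::pow(b1, t_step);
      const float bc2 = 1.0f - std::pow(b2, t_step);
      for (auto& ly : net.ly) adam_update(ly, lr, b1, b2, bc1, bc2, ef);
      ep_loss += loss;
      ++n_batch;
    }
    history(ep) = ep_loss / n_batch;
    if (verbose) {
      Rcpp::Rcout << "unet epoch " << ep + 1 << " loss " << history(ep)
                  << " at " << clock() / CLOCKS_PER_SEC << " s cpu"
                  << std::endl;
    }
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List w_out(8), b_out(8);
  for (int l = 0; l < 8; ++l) {
    w_out[l] = conv_to<mat>::from(net.ly[l].w);
    rowvec bd = conv_to<rowvec>::from(net.ly[l].b);
    b_out[l] = Rcpp::NumericVector(bd.begin(), bd.end());
  }
  return Rcpp::List::create(Rcpp::Named("w") = w_out,
                            Rcpp::Named("b") = b_out,
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::mat unet_predict_core(const arma::mat& x, Rcpp::List w0,
                            Rcpp::List b0, int base, int side,
                            int batch = 256) {
  enable_ftz_cn();
  UNet net = build_net(w0, b0, base, side);
  const fmat xf = conv_to<fmat>::from(x);
  mat out(x.n_rows, side * side);
  Cache K;
  for (uword s0 = 0; s0 < xf.n_rows; s0 += batch) {
    const uword e = std::min<uword>(s0 + batch, xf.n_rows) - 1;
    const fmat xb = xf.rows(s0, e);
    unet_forward_core(net, xb, K, false);
    out.rows(s0, e) = conv_to<mat>::from(K.out);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List unet_grad_core(const arma::mat& x, const arma::mat& y,
                          Rcpp::List w0, Rcpp::List b0, int base,
                          int side) {
  // single forward/backward pass exposing predictions, loss and gradients;
  // used to cross-check against the pure-R reference implementation
  enable_ftz_cn();
  UNet net = build_net(w0, b0, base, side);
  const fmat xb = conv_to<fmat>::from(x);
  const fmat yb = conv_to<fmat>::from(y);
  Cache K;
  unet_forward_core(net, xb, K, true);
  const double loss = unet_backward_core(net, xb, yb, K);
  Rcpp::List gw(8), gb(8);
  for (int l = 0; l < 8; ++l) {
    gw[l] = conv_to<mat>::from(net.ly[l].gw);
    rowvec g = conv_to<rowvec>::from(net.ly[l].gb);
    gb[l] = Rcpp::NumericVector(g.begin(), g.end());
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = conv_to<mat>::from(K.out),
    Rcpp::Named("loss") = loss, Rcpp::Named("gw") = gw,
    Rcpp::Named("gb") = gb);
}
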