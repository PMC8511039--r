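// Core tensor kernels for the patch-classification CNN: 4 blocks of
// (3x3 valid conv -> ReLU) x2 + 2x2/2 max-pool, then FC(12) -> FC(4) -> softmax.
// Single precision; gradients computed layer by layer for one sample at a time
// (patches are large, so per-sample GEMMs already saturate the BLAS).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

// Leaky-ReLU slope: keeps gradient flow alive in this very narrow (9-filter)
// architecture, where hard ReLU units die irrecoverably at small batch counts.
static constexpr float kLeak = 0.01f;

static fcube cube_from_r(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("input must be a 3-d array");
  fcube c(d[0], d[1], d[2]);
  const double* p = x.begin();
  float* q = c.memptr();
  for (arma::uword i = 0; i < c.n_elem; ++i) q[i] = static_cast<float>(p[i]);
  return c;
}

static fmat mat_from_r(const NumericMatrix& m) {
  fmat f(m.nrow(), m.ncol());
  const double* p = m.begin();
  float* q = f.memptr();
  for (arma::uword i = 0; i < f.n_elem; ++i) q[i] = static_cast<float>(p[i]);
  return f;
}

static fvec vec_from_r(const NumericVector& v) {
  fvec f(v.size());
  for (int i = 0; i < v.size(); ++i) f[i] = static_cast<float>(v[i]);
  return f;
}

static NumericMatrix mat_to_r(const fmat& f) {
  NumericMatrix m(f.n_rows, f.n_cols);
  const float* q = f.memptr();
  for (arma::uword i = 0; i < f.n_elem; ++i) m[i] = q[i];
  return m;
}

static NumericVector vec_to_r(const fvec& f) {
  NumericVector v(f.n_elem);
  for (arma::uword i = 0; i < f.n_elem; ++i) v[i] = f[i];
  return v;
}

// 3x3 valid-convolution patch matrix: row per output pixel (column-major over
// the output plane), column per (dr, dc, channel) kernel tap.
static fmat im2col3(const fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H - 2, ow = W - 2;
  fmat out(static_cast<arma::uword>(oh) * ow, 9 * C);
  for (int c = 0; c < C; ++c)
    for (int dc = 0; dc < 3; ++dc)
      for (int dr = 0; dr < 3; ++dr) {
        int col = c * 9 + dc * 3 + dr;
        out.col(col) =
            arma::vectorise(x.slice(c).submat(dr, dc, dr + oh - 1, dc + ow - 1));
      }
  return out;
}

// Scatter-add transpose of im2col3.
static fcube col2im3(const fmat& cols, int H, int W, int C) {
  const int oh = H - 2, ow = W - 2;
  fcube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dc = 0; dc < 3; ++dc)
      for (int dr = 0; dr < 3; ++dr) {
        int col = c * 9 + dc * 3 + dr;
        x.slice(c).submat(dr, dc, dr + oh - 1, dc + ow - 1) +=
            arma::reshape(cols.col(col), oh, ow);
      }
  return x;
}

struct ConvCache {
  fmat cols;      // im2col of the layer input
  arma::umat mask; // relu mask over (pixels x filters)
  int in_h, in_w, in_c;
};

struct PoolCache {
  arma::uvec argmax; // linear index into pre-pool cube per pooled element
  int in_h, in_w, out_h, out_w, C;
};

static fcube maxpool2(const fcube& a, PoolCache& pc) {
  const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
  const int ph = H / 2, pw = W / 2;
  pc.in_h = H; pc.in_w = W; pc.out_h = ph; pc.out_w = pw; pc.C = C;
  fcube p(ph, pw, C);
  pc.argmax.set_size(static_cast<arma::uword>(ph) * pw * C);
  arma::uword k = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < pw; ++j)
      for (int i = 0; i < ph; ++i) {
        const int r0 = 2 * i, c0 = 2 * j;
        float best = a(r0, c0, c);
        int br = r0, bc = c0;
        if (a(r0 + 1, c0, c) > best) { best = a(r0 + 1, c0, c); br = r0 + 1; bc = c0; }
        if (a(r0, c0 + 1, c) > best) { best = a(r0, c0 + 1, c); br = r0; bc = c0 + 1; }
        if (a(r0 + 1, c0 + 1, c) > best) { best = a(r0 + 1, c0 + 1, c); br = r0 + 1; bc = c0 + 1; }
        p(i, j, c) = best;
        pc.argmax[k++] = static_cast<arma::uword>(br) +
                         static_cast<arma::uword>(bc) * H +
                         static_cast<arma::uword>(c) * H * W;
      }
  return p;
}

struct Net {
  std::vector<fmat> convW; std::vector<fvec> convB;
  fmat W1; fvec b1; fmat W2; fvec b2;
};

static Net net_from_r(const List& params) {
  Net n;
  List conv = params["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    List layer = conv[i];
    n.convW.push_back(mat_from_r(layer["W"]));
    n.convB.push_back(vec_from_r(layer["b"]));
  }
  List fc1 = params["fc1"], fc2 = params["fc2"];
  n.W1 = mat_from_r(fc1["W"]); n.b1 = vec_from_r(fc1["b"]);
  n.W2 = mat_from_r(fc2["W"]); n.b2 = vec_from_r(fc2["b"]);
  return n;
}

struct FwdState {
  std::vector<ConvCache> cc;
  std::vector<PoolCache> pc;
  std::vector<fcube> drop;   // inverted-dropout masks after each pool
  fvec flat, h1pre, h1, h1drop, probs;
  fvec fc1mask;              // dropout mask after fc1
  int last_h, last_w;
};

static fvec softmax(const fvec& z) {
  fvec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

static fvec forward(const fcube& x, const Net& net, bool train, double rate,
                    uint32_t seed, FwdState* st) {
  std::mt19937 rng(seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float keep = 1.0f - static_cast<float>(rate);
  fcube a = x;
  int li = 0;
  for (int blk = 0; blk < 4; ++blk) {
    for (int k = 0; k < 2; ++k, ++li) {
      if ((int)a.n_rows < 3 || (int)a.n_cols < 3)
        stop("input collapsed before conv layer %d", li + 1);
      ConvCache cc;
      cc.in_h = a.n_rows; cc.in_w = a.n_cols; cc.in_c = a.n_slices;
      fmat cols = im2col3(a);
      fmat pre = cols * net.convW[li];
      pre.each_row() += net.convB[li].t();
      arma::umat mask = pre > 0.0f;
      pre.transform([](float v) { return v > 0.0f ? v : kLeak * v; });
      fcube nxt(a.n_rows - 2, a.n_cols - 2, net.convW[li].n_cols);
      std::memcpy(nxt.memptr(), pre.memptr(), pre.n_elem * sizeof(float));
      if (st) { cc.cols = std::move(cols); cc.mask = std::move(mask); st->cc.push_back(std::move(cc)); }
      a = std::move(nxt);
    }
    if ((int)a.n_rows < 2 || (int)a.n_cols < 2)
      stop("input collapsed at max-pool %d", blk + 1);
    PoolCache pcc;
    a = maxpool2(a, pcc);
    if (st) st->pc.push_back(std::move(pcc));
    // dropout on the conv stack output only (blk 3 feeds the flatten);
    // dropping early pool activations makes small-batch gradients too noisy
    // for this 9-filter architecture to train
    if (train && rate > 0 && blk == 3) {
      fcube m(a.n_rows, a.n_cols, a.n_slices);
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m.memptr()[i] = (unif(rng) >= rate) ? 1.0f / keep : 0.0f;
      a %= m;
      if (st) st->drop.push_back(std::move(m));
    } else if (st) {
      st->drop.push_back(fcube());
    }
  }
  fvec flat = arma::vectorise(a);
  if ((int)flat.n_elem != (int)net.W1.n_rows)
    stop("flatten length %d does not match fc1 fan-in %d",
         (int)flat.n_elem, (int)net.W1.n_rows);
  fvec h1pre = net.W1.t() * flat + net.b1;
  fvec h1 = h1pre;
  h1.transform([](float v) { return v > 0.0f ? v : kLeak * v; });
  fvec fc1mask(h1.n_elem, arma::fill::ones);
  if (train && rate > 0) {
    for (arma::uword i = 0; i < fc1mask.n_elem; ++i)
      fc1mask[i] = (unif(rng) >= rate) ? 1.0f / keep : 0.0f;
  }
  fvec h1d = h1 % fc1mask;
  fvec z = net.W2.t() * h1d + net.b2;
  fvec probs = softmax(z);
  if (st) {
    st->flat = std::move(flat); st->h1pre = std::move(h1pre);
    st->h1 = std::move(h1); st->h1drop = std::move(h1d);
    st->fc1mask = std::move(fc1mask); st->probs = probs;
    st->last_h = a.n_rows; st->last_w = a.n_cols;
  }
  return probs;
}

//' @noRd
// [[Rcpp::export(name = "cnn_forward_cpp")]]
NumericVector cnn_forward_cpp(NumericVector x, List params) {
  fcube a = cube_from_r(x);
  Net net = net_from_r(params);
  fvec p = forward(a, net, false, 0.0, 0u, nullptr);
  return vec_to_r(p);
}

// Inference-mode flatten features (conv stack output) for one patch; used to
// cache features for the head pre-fit, where the conv layers are frozen.
//' @noRd
// [[Rcpp::export(name = "cnn_flat_cpp")]]
NumericVector cnn_flat_cpp(NumericVector x, List params) {
  fcube a = cube_from_r(x);
  Net net = net_from_r(params);
  FwdState st;
  forward(a, net, false, 0.0, 0u, &st);
  return vec_to_r(st.flat);
}

// Runtime spatial-size trace of an actual forward pass: the side length of
// every conv and pool output, in layer order, plus the flatten length.
//' @noRd
// [[Rcpp::export(name = "cnn_trace_cpp")]]
IntegerVector cnn_trace_cpp(NumericVector x, List params) {
  fcube a = cube_from_r(x);
  Net net = net_from_r(params);
  FwdState st;
  forward(a, net, false, 0.0, 0u, &st);
  std::vector<int> sizes;
  for (int blk = 0; blk < 4; ++blk) {
    sizes.push_back(st.cc[2 * blk].in_h - 2);
    sizes.push_back(st.cc[2 * blk + 1].in_h - 2);
    sizes.push_back(st.pc[blk].out_h);
  }
  sizes.push_back(static_cast<int>(st.flat.n_elem));
  return wrap(sizes);
}

// Forward + backward for one labelled sample; label in 1..K.
// head_only skips the convolutional backward pass (gradients zero there),
// used for the head-warmup phase of training.
//' @noRd
// [[Rcpp::export(name = "cnn_grad_cpp")]]
List cnn_grad_cpp(NumericVector x, List params, int label, double dropout_rate,
                  int seed, bool head_only = false) {
  fcube a0 = cube_from_r(x);
  Net net = net_from_r(params);
  FwdState st;
  fvec probs = forward(a0, net, dropout_rate > 0, dropout_rate,
                       static_cast<uint32_t>(seed), &st);
  const int K = probs.n_elem;
  if (label < 1 || label > K) stop("label out of range 1..%d", K);
  const double eps = 1e-12;
  double loss = -std::log(std::max(static_cast<double>(probs[label - 1]), eps));

  fvec dz = probs; dz[label - 1] -= 1.0f;
  fmat dW2 = st.h1drop * dz.t();
  fvec db2 = dz;
  fvec dh1 = (net.W2 * dz) % st.fc1mask;
  fvec dh1pre = dh1;
  for (arma::uword i = 0; i < dh1pre.n_elem; ++i)
    if (st.h1pre[i] <= 0.0f) dh1pre[i] *= kLeak;
  fmat dW1 = st.flat * dh1pre.t();
  fvec db1 = dh1pre;
  fvec dflat = net.W1 * dh1pre;

  std::vector<fmat> dconvW(8);
  std::vector<fvec> dconvB(8);
  if (head_only) {
    for (int i = 0; i < 8; ++i) {
      dconvW[i] = fmat(net.convW[i].n_rows, net.convW[i].n_cols, arma::fill::zeros);
      dconvB[i] = fvec(net.convB[i].n_elem, arma::fill::zeros);
    }
    List gconv0(8);
    for (int i = 0; i < 8; ++i)
      gconv0[i] = List::create(_["W"] = mat_to_r(dconvW[i]),
                               _["b"] = vec_to_r(dconvB[i]));
    return List::create(
        _["loss"] = loss,
        _["probs"] = vec_to_r(probs),
        _["grads"] = List::create(
            _["conv"] = gconv0,
            _["fc1"] = List::create(_["W"] = mat_to_r(dW1), _["b"] = vec_to_r(db1)),
            _["fc2"] = List::create(_["W"] = mat_to_r(dW2), _["b"] = vec_to_r(db2))));
  }

  fcube da(st.last_h, st.last_w, net.convW.back().n_cols);
  std::memcpy(da.memptr(), dflat.memptr(), dflat.n_elem * sizeof(float));

  int li = 7;
  for (int blk = 3; blk >= 0; --blk) {
    if (st.drop[blk].n_elem > 0) da %= st.drop[blk];
    const PoolCache& pcc = st.pc[blk];
    fcube dpre(pcc.in_h, pcc.in_w, pcc.C, arma::fill::zeros);
    const float* src = da.memptr();
    for (arma::uword k = 0; k < pcc.argmax.n_elem; ++k)
      dpre.memptr()[pcc.argmax[k]] += src[k];
    for (int k = 1; k >= 0; --k, --li) {
      const ConvCache& cc = st.cc[li];
      const arma::uword npix = static_cast<arma::uword>(cc.in_h - 2) * (cc.in_w - 2);
      fmat dout(npix, net.convW[li].n_cols);
      std::memcpy(dout.memptr(), dpre.memptr(), dpre.n_elem * sizeof(float));
      {
        fmat mf = arma::conv_to<fmat>::from(cc.mask);
        mf.transform([](float v) { return v > 0.0f ? 1.0f : kLeak; });
        dout %= mf;
      }
      dconvW[li] = cc.cols.t() * dout;
      dconvB[li] = arma::sum(dout, 0).t();
      fmat dcols = dout * net.convW[li].t();
      dpre = col2im3(dcols, cc.in_h, cc.in_w, cc.in_c);
    }
    da = std::move(dpre);
  }

  List gconv(8);
  for (int i = 0; i < 8; ++i)
    gconv[i] = List::create(_["W"] = mat_to_r(dconvW[i]),
                            _["b"] = vec_to_r(dconvB[i]));
  return List::create(
      _["loss"] = loss,
      _["probs"] = vec_to_r(probs),
      _["grads"] = List::create(
          _["conv"] = gconv,
          _["fc1"] = List::create(_["W"] = mat_to_r(dW1), _["b"] = vec_to_r(db1)),
          _["fc2"] = List::create(_["W"] = mat_to_r(dW2), _["b"] = vec_to_r(db2))));
}
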