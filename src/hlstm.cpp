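// Hierarchical bidirectional LSTM for sentence-level relation detection.
//
// Architecture: four bottom many-to-one bi-LSTMs (three sentence segments +
// the shortest dependency path) feed, interleaved with the two fixed entity
// embeddings, a six-step top bi-LSTM whose output passes through a linear
// layer and a binary softmax. POS and dependency-tag embedding tables are
// trained jointly; word embeddings, attention weights and position one-hots
// arrive precomputed from R. Training is per-example Adam on the cross-
// entropy loss with inverted dropout (input features / top output).

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

namespace {

struct LSTMParams {
  mat Wf, Uf; vec bf;  // forward direction, gates stacked [i;f;g;o]
  mat Wb, Ub; vec bb;  // backward direction
};

struct Model {
  mat pos_emb, dep_emb;
  LSTMParams lstm[5];  // seg1, seg2, seg3, sdp, top
  mat ff_W; vec ff_b;
};

const char* kLstmNames[5] = {"s1", "s2", "s3", "sdp", "top"};

Model model_from_list(const List& params) {
  Model m;
  m.pos_emb = as<mat>(params["pos_emb"]);
  m.dep_emb = as<mat>(params["dep_emb"]);
  for (int k = 0; k < 5; ++k) {
    std::string p(kLstmNames[k]);
    m.lstm[k].Wf = as<mat>(params[p + "_Wf"]);
    m.lstm[k].Uf = as<mat>(params[p + "_Uf"]);
    m.lstm[k].bf = as<vec>(params[p + "_bf"]);
    m.lstm[k].Wb = as<mat>(params[p + "_Wb"]);
    m.lstm[k].Ub = as<mat>(params[p + "_Ub"]);
    m.lstm[k].bb = as<vec>(params[p + "_bb"]);
  }
  m.ff_W = as<mat>(params["ff_W"]);
  m.ff_b = as<vec>(params["ff_b"]);
  return m;
}

List model_to_list(const Model& m) {
  List out;
  out["pos_emb"] = m.pos_emb;
  out["dep_emb"] = m.dep_emb;
  for (int k = 0; k < 5; ++k) {
    std::string p(kLstmNames[k]);
    out[p + "_Wf"] = m.lstm[k].Wf; out[p + "_Uf"] = m.lstm[k].Uf;
    out[p + "_bf"] = m.lstm[k].bf; out[p + "_Wb"] = m.lstm[k].Wb;
    out[p + "_Ub"] = m.lstm[k].Ub; out[p + "_bb"] = m.lstm[k].bb;
  }
  out["ff_W"] = m.ff_W; out["ff_b"] = m.ff_b;
  return out;
}

Model model_zeros_like(const Model& m) {
  Model g;
  g.pos_emb = arma::zeros<mat>(m.pos_emb.n_rows, m.pos_emb.n_cols);
  g.dep_emb = arma::zeros<mat>(m.dep_emb.n_rows, m.dep_emb.n_cols);
  for (int k = 0; k < 5; ++k) {
    g.lstm[k].Wf = arma::zeros<mat>(m.lstm[k].Wf.n_rows, m.lstm[k].Wf.n_cols);
    g.lstm[k].Uf = arma::zeros<mat>(m.lstm[k].Uf.n_rows, m.lstm[k].Uf.n_cols);
    g.lstm[k].bf = arma::zeros<vec>(m.lstm[k].bf.n_elem);
    g.lstm[k].Wb = arma::zeros<mat>(m.lstm[k].Wb.n_rows, m.lstm[k].Wb.n_cols);
    g.lstm[k].Ub = arma::zeros<mat>(m.lstm[k].Ub.n_rows, m.lstm[k].Ub.n_cols);
    g.lstm[k].bb = arma::zeros<vec>(m.lstm[k].bb.n_elem);
  }
  g.ff_W = arma::zeros<mat>(m.ff_W.n_rows, m.ff_W.n_cols);
  g.ff_b = arma::zeros<vec>(m.ff_b.n_elem);
  return g;
}

std::vector<mat*> model_fields(Model& m) {
  std::vector<mat*> f;
  f.push_back(&m.pos_emb); f.push_back(&m.dep_emb);
  for (int k = 0; k < 5; ++k) {
    f.push_back(&m.lstm[k].Wf); f.push_back(&m.lstm[k].Uf);
    f.push_back(&m.lstm[k].Wb); f.push_back(&m.lstm[k].Ub);
  }
  f.push_back(&m.ff_W);
  return f;
}
std::vector<vec*> model_vec_fields(Model& m) {
  std::vector<vec*> f;
  for (int k = 0; k < 5; ++k) { f.push_back(&m.lstm[k].bf); f.push_back(&m.lstm[k].bb); }
  f.push_back(&m.ff_b);
  return f;
}

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---- one-direction LSTM with cached gates (for BPTT) --------------------

struct LSTMCache {
  mat X;                // T x D inputs as used (dropout applied)
  mat i, f, g, o, c, h; // T x H
  int T = 0;
};

// many-to-one: returns last hidden state; X rows consumed in given order
vec lstm_forward(const mat& X, const mat& W, const mat& U, const vec& b,
                 LSTMCache* cache) {
  int T = X.n_rows;
  int H = U.n_cols;
  vec h = arma::zeros<vec>(H), c = arma::zeros<vec>(H);
  if (cache) {
    cache->X = X; cache->T = T;
    cache->i.set_size(T, H); cache->f.set_size(T, H); cache->g.set_size(T, H);
    cache->o.set_size(T, H); cache->c.set_size(T, H); cache->h.set_size(T, H);
  }
  for (int t = 0; t < T; ++t) {
    vec z = W * X.row(t).t() + U * h + b;
    vec i = sigmoid(z.subvec(0, H - 1));
    vec f = sigmoid(z.subvec(H, 2 * H - 1));
    vec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = sigmoid(z.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    if (cache) {
      cache->i.row(t) = i.t(); cache->f.row(t) = f.t();
      cache->g.row(t) = g.t(); cache->o.row(t) = o.t();
      cache->c.row(t) = c.t(); cache->h.row(t) = h.t();
    }
  }
  return h;  // zeros when T == 0
}

// BPTT for the many-to-one direction; dh_last is dL/d(h_T).
// Accumulates parameter grads into gW,gU,gb and returns dL/dX.
mat lstm_backward(const LSTMCache& cc, const mat& W, const mat& U,
                  vec dh_last, mat& gW, mat& gU, vec& gb) {
  int T = cc.T;
  int H = U.n_cols;
  mat dX(T, cc.X.n_cols, arma::fill::zeros);
  vec dh = dh_last;
  vec dc = arma::zeros<vec>(H);
  for (int t = T - 1; t >= 0; --t) {
    vec i = cc.i.row(t).t(), f = cc.f.row(t).t(), g = cc.g.row(t).t(),
        o = cc.o.row(t).t(), c = cc.c.row(t).t();
    vec tc = arma::tanh(c);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec cprev = (t > 0) ? vec(cc.c.row(t - 1).t()) : arma::zeros<vec>(H);
    vec di = dc % g;
    vec df = dc % cprev;
    vec dg = dc % i;
    vec dz(4 * H);
    dz.subvec(0, H - 1)         = di % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    gW += dz * cc.X.row(t);
    vec hprev = (t > 0) ? vec(cc.h.row(t - 1).t()) : arma::zeros<vec>(H);
    gU += dz * hprev.t();
    gb += dz;
    dX.row(t) = (W.t() * dz).t();
    dh = U.t() * dz;
    dc = dc % f;
  }
  return dX;
}

struct BiCache { LSTMCache fwd, bwd; };

// many-to-one bi-LSTM: concat(last forward state, last backward state)
vec bilstm_forward(const mat& X, const LSTMParams& p, BiCache* cache) {
  vec hf = lstm_forward(X, p.Wf, p.Uf, p.bf, cache ? &cache->fwd : nullptr);
  mat Xr = arma::flipud(X);
  vec hb = lstm_forward(Xr, p.Wb, p.Ub, p.bb, cache ? &cache->bwd : nullptr);
  return arma::join_cols(hf, hb);
}

mat bilstm_backward(const BiCache& cc, const LSTMParams& p, const vec& dh,
                    LSTMParams& g) {
  int H = p.Uf.n_cols;
  mat dXf = lstm_backward(cc.fwd, p.Wf, p.Uf, dh.subvec(0, H - 1),
                          g.Wf, g.Uf, g.bf);
  mat dXb = lstm_backward(cc.bwd, p.Wb, p.Ub, dh.subvec(H, 2 * H - 1),
                          g.Wb, g.Ub, g.bb);
  return dXf + arma::flipud(dXb);
}

// ---- example assembly ---------------------------------------------------

struct SegInput {
  mat word;            // T x word_dim, attention-weighted
  arma::ivec pos, dep; // 1-based ids into embedding tables (0 = none)
  mat posf;            // T x 20
};

struct Example {
  SegInput seg[4];
  vec e1, e2;
};

Example example_from_list(const List& ex) {
  Example e;
  List segs = ex["segs"];
  for (int s = 0; s < 4; ++s) {
    List sl = segs[s];
    e.seg[s].word = as<mat>(sl["word"]);
    e.seg[s].pos = as<arma::ivec>(sl["pos"]);
    e.seg[s].dep = as<arma::ivec>(sl["dep"]);
    e.seg[s].posf = as<mat>(sl["posf"]);
  }
  e.e1 = as<vec>(ex["e1"]);
  e.e2 = as<vec>(ex["e2"]);
  return e;
}

// features per token: [word | pos_emb | dep_emb | position one-hots]
mat seg_features(const SegInput& s, const Model& m) {
  int T = s.word.n_rows;
  int D = s.word.n_cols + m.pos_emb.n_cols + m.dep_emb.n_cols + s.posf.n_cols;
  mat X(T, D, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    int off = 0;
    X(t, arma::span(off, off + s.word.n_cols - 1)) = s.word.row(t);
    off += s.word.n_cols;
    if (s.pos[t] > 0)
      X(t, arma::span(off, off + m.pos_emb.n_cols - 1)) = m.pos_emb.row(s.pos[t] - 1);
    off += m.pos_emb.n_cols;
    if (s.dep[t] > 0)
      X(t, arma::span(off, off + m.dep_emb.n_cols - 1)) = m.dep_emb.row(s.dep[t] - 1);
    off += m.dep_emb.n_cols;
    X(t, arma::span(off, off + s.posf.n_cols - 1)) = s.posf.row(t);
  }
  return X;
}

struct ForwardCache {
  BiCache seg[4];
  BiCache top;
  mat seg_X[4];       // inputs as used (post-dropout)
  mat seg_mask[4];    // dropout masks (empty when not training)
  mat bottom;         // 4 x 2H
  mat top_in;         // 6 x 2H
  vec top_out;        // 2H (post-dropout when training)
  vec out_mask;
  vec probs;          // 2
};

vec softmax2(const vec& logits) {
  vec z = logits - logits.max();
  vec e = arma::exp(z);
  return e / arma::accu(e);
}

// rng-driven inverted dropout mask (values 0 or 1/keep)
mat dropout_mask(int r, int c, double keep, std::mt19937& rng) {
  mat msk(r, c);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j)
      msk(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
  return msk;
}

vec forward_pass(const Model& m, const Example& e, ForwardCache* cc,
                 bool training, double keep_in, double keep_out,
                 std::mt19937* rng) {
  int H = m.lstm[0].Uf.n_cols;
  mat bottom(4, 2 * H);
  ForwardCache local;
  ForwardCache* c = cc ? cc : &local;
  for (int s = 0; s < 4; ++s) {
    mat X = seg_features(e.seg[s], m);
    if (training && keep_in < 1.0 && X.n_rows > 0) {
      mat msk = dropout_mask(X.n_rows, X.n_cols, keep_in, *rng);
      c->seg_mask[s] = msk;
      X %= msk;
    }
    c->seg_X[s] = X;
    bottom.row(s) = bilstm_forward(X, m.lstm[s], &c->seg[s]).t();
  }
  c->bottom = bottom;
  // top input in sentence order: Seq1, E1, Seq2, E2, Seq3, SDP
  mat top_in(6, 2 * H);
  top_in.row(0) = bottom.row(0);
  top_in.row(1) = e.e1.t();
  top_in.row(2) = bottom.row(1);
  top_in.row(3) = e.e2.t();
  top_in.row(4) = bottom.row(2);
  top_in.row(5) = bottom.row(3);
  c->top_in = top_in;
  vec top_out = bilstm_forward(top_in, m.lstm[4], &c->top);
  if (training && keep_out < 1.0) {
    mat msk = dropout_mask(top_out.n_elem, 1, keep_out, *rng);
    c->out_mask = msk.col(0);
    top_out %= c->out_mask;
  }
  c->top_out = top_out;
  c->probs = softmax2(m.ff_W * top_out + m.ff_b);
  return c->probs;
}

// cross-entropy backward; accumulates grads into g
double backward_pass(const Model& m, const Example& e, const ForwardCache& cc,
                     int label, Model& g) {
  double loss = -std::log(std::max(cc.probs(label), 1e-12));
  vec dlogits = cc.probs;
  dlogits(label) -= 1.0;
  g.ff_W += dlogits * cc.top_out.t();
  g.ff_b += dlogits;
  vec dtop = m.ff_W.t() * dlogits;
  if (cc.out_mask.n_elem > 0) dtop %= cc.out_mask;
  mat dtop_in = bilstm_backward(cc.top, m.lstm[4], dtop, g.lstm[4]);
  // rows 1 and 3 are the fixed entity embeddings; rows 0,2,4,5 feed back
  int seg_row[4] = {0, 2, 4, 5};
  for (int s = 0; s < 4; ++s) {
    if (cc.seg_X[s].n_rows == 0) {
      // empty segment: nothing below to update, but the (constant) zero
      // output still received gradient; it has no parameters upstream
      continue;
    }
    vec dh = dtop_in.row(seg_row[s]).t();
    mat dX = bilstm_backward(cc.seg[s], m.lstm[s], dh, g.lstm[s]);
    if (cc.seg_mask[s].n_elem > 0) dX %= cc.seg_mask[s];
    // scatter gradients into the trainable pos/dep embedding tables
    int off = e.seg[s].word.n_cols;
    int P = m.pos_emb.n_cols, Dd = m.dep_emb.n_cols;
    for (arma::uword t = 0; t < dX.n_rows; ++t) {
      if (e.seg[s].pos[t] > 0)
        g.pos_emb.row(e.seg[s].pos[t] - 1) += dX(t, arma::span(off, off + P - 1));
      if (e.seg[s].dep[t] > 0)
        g.dep_emb.row(e.seg[s].dep[t] - 1) += dX(t, arma::span(off + P, off + P + Dd - 1));
    }
  }
  return loss;
}

}  // namespace

// [[Rcpp::export]]
List cpp_hlstm_forward(List params, List example, bool internals = false) {
  Model m = model_from_list(params);
  Example e = example_from_list(example);
  ForwardCache cc;
  vec probs = forward_pass(m, e, &cc, false, 1.0, 1.0, nullptr);
  List out = List::create(_["probs"] = probs);
  if (internals) {
    out["bottom"] = cc.bottom;
    out["top_input"] = cc.top_in;
    out["top_output"] = cc.top_out;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hlstm_predict(List params, List examples) {
  Model m = model_from_list(params);
  int n = examples.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Example e = example_from_list(examples[i]);
    vec probs = forward_pass(m, e, nullptr, false, 1.0, 1.0, nullptr);
    out[i] = probs(1);
  }
  return out;
}

// loss and exact gradients for one example (no dropout); used by the
// finite-difference gradient check in the test suite
// [[Rcpp::export]]
List cpp_hlstm_grad(List params, List example, int label) {
  Model m = model_from_list(params);
  Example e = example_from_list(example);
  ForwardCache cc;
  forward_pass(m, e, &cc, false, 1.0, 1.0, nullptr);
  Model g = model_zeros_like(m);
  double loss = backward_pass(m, e, cc, label, g);
  return List::create(_["loss"] = loss, _["grads"] = model_to_list(g));
}

// [[Rcpp::export]]
double cpp_hlstm_loss(List params, List example, int label) {
  Model m = model_from_list(params);
  Example e = example_from_list(example);
  ForwardCache cc;
  forward_pass(m, e, &cc, false, 1.0, 1.0, nullptr);
  return -std::log(std::max(cc.probs(label), 1e-12));
}

void model_zero_inplace(Model& g) {
  for (mat* p : model_fields(g)) p->zeros();
  for (vec* p : model_vec_fields(g)) p->zeros();
}

// Minibatch Adam on shuffled data; deterministic for a given seed.
// [[Rcpp::export]]
List cpp_hlstm_train(List params, List examples, IntegerVector labels,
                     double lr, int epochs, double keep_in, double keep_out,
                     int seed, int batch_size = 16, double beta1 = 0.9,
                     double beta2 = 0.999, double eps = 1e-8) {
  Model m = model_from_list(params);
  int n = examples.size();
  std::vector<Example> data(n);
  for (int i = 0; i < n; ++i) data[i] = example_from_list(examples[i]);

  Model g = model_zeros_like(m);
  Model madam = model_zeros_like(m), vadam = model_zeros_like(m);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<mat*> pm = model_fields(m), pg = model_fields(g),
                    pmm = model_fields(madam), pv = model_fields(vadam);
  std::vector<vec*> vm = model_vec_fields(m), vg = model_vec_fields(g),
                    vmm = model_vec_fields(madam), vv = model_vec_fields(vadam);

  NumericVector loss_trace(epochs);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(n, start + batch_size);
      model_zero_inplace(g);
      for (int b = start; b < stop; ++b) {
        int idx = order[b];
        ForwardCache cc;
        forward_pass(m, data[idx], &cc, true, keep_in, keep_out, &rng);
        total += backward_pass(m, data[idx], cc, labels[idx], g);
      }
      double inv = 1.0 / (stop - start);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t k = 0; k < pm.size(); ++k) {
        *pmm[k] = beta1 * (*pmm[k]) + (1 - beta1) * inv * (*pg[k]);
        *pv[k] = beta2 * (*pv[k]) + (1 - beta2) * arma::square(inv * (*pg[k]));
        *pm[k] -= lr * ((*pmm[k]) / bc1) / (arma::sqrt((*pv[k]) / bc2) + eps);
      }
      for (size_t k = 0; k < vm.size(); ++k) {
        *vmm[k] = beta1 * (*vmm[k]) + (1 - beta1) * inv * (*vg[k]);
        *vv[k] = beta2 * (*vv[k]) + (1 - beta2) * arma::square(inv * (*vg[k]));
        *vm[k] -= lr * ((*vmm[k]) / bc1) / (arma::sqrt((*vv[k]) / bc2) + eps);
      }
    }
    loss_trace[ep] = total / std::max(n, 1);
  }
  return List::create(_["params"] = model_to_list(m),
                      _["loss_trace"] = loss_trace);
}
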