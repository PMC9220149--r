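// Bidirectional LSTM encoder with a linear-chain CRF output layer.
// Single-threaded, deterministic given the seed. Parameters travel as an
// R list of matrices so the R side owns checkpointing and early stopping.
//
// Conventions:
//   tokens/tags arrive 0-based from the R wrappers
//   K tags; transition matrix Tr is (K+2)x(K+2) with START = K, STOP = K+1
//   `allowed` is a 0/1 matrix of the same shape; forbidden transitions are
//   fixed at NEG_INF in the effective matrix and receive no gradient
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double NEG_INF = -1e30;

struct Params {
  mat E;                // D x V token embeddings
  mat Wf, Uf; vec bf;   // forward LSTM: 4H x D, 4H x H, 4H
  mat Wb, Ub; vec bb;   // backward LSTM
  mat Wp; vec bp;       // projection: K x 2H, K
  mat Tr;               // (K+2) x (K+2) learned transition scores
  int D, H, K, V;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.E = Rcpp::as<mat>(p["E"]);
  q.Wf = Rcpp::as<mat>(p["Wf"]); q.Uf = Rcpp::as<mat>(p["Uf"]);
  q.bf = Rcpp::as<vec>(p["bf"]);
  q.Wb = Rcpp::as<mat>(p["Wb"]); q.Ub = Rcpp::as<mat>(p["Ub"]);
  q.bb = Rcpp::as<vec>(p["bb"]);
  q.Wp = Rcpp::as<mat>(p["Wp"]); q.bp = Rcpp::as<vec>(p["bp"]);
  q.Tr = Rcpp::as<mat>(p["Tr"]);
  q.D = q.E.n_rows; q.V = q.E.n_cols;
  q.H = q.Uf.n_cols; q.K = q.Wp.n_rows;
  return q;
}

static Rcpp::List pack(const Params& q) {
  return Rcpp::List::create(
      Rcpp::Named("E") = q.E, Rcpp::Named("Wf") = q.Wf,
      Rcpp::Named("Uf") = q.Uf, Rcpp::Named("bf") = q.bf,
      Rcpp::Named("Wb") = q.Wb, Rcpp::Named("Ub") = q.Ub,
      Rcpp::Named("bb") = q.bb, Rcpp::Named("Wp") = q.Wp,
      Rcpp::Named("bp") = q.bp, Rcpp::Named("Tr") = q.Tr);
}

struct Grads {
  mat E, Wf, Uf, Wb, Ub, Wp, Tr;
  vec bf, bb, bp;
  void zero(const Params& q) {
    E.zeros(q.D, q.V);
    Wf.zeros(4 * q.H, q.D); Uf.zeros(4 * q.H, q.H); bf.zeros(4 * q.H);
    Wb.zeros(4 * q.H, q.D); Ub.zeros(4 * q.H, q.H); bb.zeros(4 * q.H);
    Wp.zeros(q.K, 2 * q.H); bp.zeros(q.K);
    Tr.zeros(q.K + 2, q.K + 2);
  }
};

struct LstmCache {
  mat I, F, G, O, C, Hh; // H x T gate activations, cell and hidden states
};

static void lstm_forward(const mat& W, const mat& U, const vec& b,
                         const mat& X, LstmCache& c) {
  int H = U.n_cols, T = X.n_cols;
  c.I.set_size(H, T); c.F.set_size(H, T); c.G.set_size(H, T);
  c.O.set_size(H, T); c.C.set_size(H, T); c.Hh.set_size(H, T);
  vec h(H, fill::zeros), cc(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec z = W * X.col(t) + U * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    cc = f % cc + i % g;
    h = o % tanh(cc);
    c.I.col(t) = i; c.F.col(t) = f; c.G.col(t) = g; c.O.col(t) = o;
    c.C.col(t) = cc; c.Hh.col(t) = h;
  }
}

// backward pass through one LSTM direction; dH is the gradient arriving at
// the hidden states (H x T); accumulates into dW/dU/db and returns dX
static mat lstm_backward(const mat& W, const mat& U, const LstmCache& c,
                         const mat& X, const mat& dH,
                         mat& dW, mat& dU, vec& db) {
  int H = U.n_cols, T = X.n_cols;
  mat dX(X.n_rows, T, fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.col(t) + dh_next;
    vec tc = tanh(c.C.col(t));
    vec dc = dc_next + dh % c.O.col(t) % (1.0 - tc % tc);
    vec do_ = dh % tc;
    vec di = dc % c.G.col(t);
    vec c_prev = (t > 0) ? vec(c.C.col(t - 1)) : vec(H, fill::zeros);
    vec df = dc % c_prev;
    vec dg = dc % c.I.col(t);
    vec dz(4 * H);
    dz.subvec(0, H - 1) = di % c.I.col(t) % (1.0 - c.I.col(t));
    dz.subvec(H, 2 * H - 1) = df % c.F.col(t) % (1.0 - c.F.col(t));
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - c.G.col(t) % c.G.col(t));
    dz.subvec(3 * H, 4 * H - 1) = do_ % c.O.col(t) % (1.0 - c.O.col(t));
    vec h_prev = (t > 0) ? vec(c.Hh.col(t - 1)) : vec(H, fill::zeros);
    dW += dz * X.col(t).t();
    dU += dz * h_prev.t();
    db += dz;
    dX.col(t) = W.t() * dz;
    dh_next = U.t() * dz;
    dc_next = dc % c.F.col(t);
  }
  return dX;
}

static mat effective_transitions(const Params& q, const mat& allowed) {
  mat tre = q.Tr;
  tre.elem(find(allowed == 0)).fill(NEG_INF);
  return tre;
}

static double lse(const vec& x) {
  double m = x.max();
  if (m <= NEG_INF / 2) return NEG_INF;
  return m + std::log(sum(exp(x - m)));
}

// emissions for one token sequence (K x T), optional dropout mask applied
// to the concatenated hidden states; caches returned for backprop
struct SeqForward {
  mat X, Hcat, Emis, Drop;
  LstmCache fwd, bwd;
};

static void seq_forward(const Params& q, const uvec& seq, const mat* drop,
                        SeqForward& sf) {
  int T = seq.n_elem;
  sf.X.set_size(q.D, T);
  for (int t = 0; t < T; ++t) sf.X.col(t) = q.E.col(seq[t]);
  lstm_forward(q.Wf, q.Uf, q.bf, sf.X, sf.fwd);
  mat Xr = fliplr(sf.X);
  lstm_forward(q.Wb, q.Ub, q.bb, Xr, sf.bwd);
  sf.Hcat.set_size(2 * q.H, T);
  sf.Hcat.rows(0, q.H - 1) = sf.fwd.Hh;
  sf.Hcat.rows(q.H, 2 * q.H - 1) = fliplr(sf.bwd.Hh);
  if (drop != nullptr) {
    sf.Drop = *drop;
    sf.Hcat %= sf.Drop;
  }
  sf.Emis = q.Wp * sf.Hcat;
  sf.Emis.each_col() += q.bp;
}

// CRF forward-backward: returns nll and fills dEmis (K x T) and dTr with
// the gradients of the nll for this sequence
static double crf_nll_grad(const mat& emis, const mat& tre,
                           const mat& allowed, const uvec& tags,
                           mat& dEmis, mat& dTr) {
  int K = emis.n_rows, T = emis.n_cols;
  int START = K, STOP = K + 1;
  mat alpha(K, T), beta(K, T);
  alpha.col(0) = tre.submat(START, 0, START, K - 1).t() + emis.col(0);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      alpha(j, t) = lse(alpha.col(t - 1) + tre.submat(0, j, K - 1, j)) +
        emis(j, t);
    }
  }
  double logZ = lse(alpha.col(T - 1) + tre.submat(0, STOP, K - 1, STOP));
  beta.col(T - 1) = tre.submat(0, STOP, K - 1, STOP);
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      beta(i, t) = lse(tre.submat(i, 0, i, K - 1).t() + emis.col(t + 1) +
                       beta.col(t + 1));
    }
  }
  // gold score
  double gold = tre(START, tags[0]);
  for (int t = 0; t < T; ++t) gold += emis(tags[t], t);
  for (int t = 1; t < T; ++t) gold += tre(tags[t - 1], tags[t]);
  gold += tre(tags[T - 1], STOP);

  dEmis.set_size(K, T);
  for (int t = 0; t < T; ++t) {
    dEmis.col(t) = exp(alpha.col(t) + beta.col(t) - logZ);
    dEmis(tags[t], t) -= 1.0;
  }
  // transition expectations (allowed entries only)
  if (allowed(START, tags[0]) != 0) {
    vec p0 = exp(tre.submat(START, 0, START, K - 1).t() + emis.col(0) +
                 beta.col(0) - logZ);
    for (int j = 0; j < K; ++j) {
      if (allowed(START, j) != 0) dTr(START, j) += p0(j);
    }
    dTr(START, tags[0]) -= 1.0;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      if (alpha(i, t) <= NEG_INF / 2) continue;
      for (int j = 0; j < K; ++j) {
        if (allowed(i, j) == 0) continue;
        dTr(i, j) += std::exp(alpha(i, t) + tre(i, j) + emis(j, t + 1) +
                              beta(j, t + 1) - logZ);
      }
    }
    dTr(tags[t], tags[t + 1]) -= 1.0;
  }
  vec pT = exp(alpha.col(T - 1) + tre.submat(0, STOP, K - 1, STOP) - logZ);
  for (int i = 0; i < K; ++i) {
    if (allowed(i, STOP) != 0) dTr(i, STOP) += pT(i);
  }
  dTr(tags[T - 1], STOP) -= 1.0;
  return logZ - gold;
}

// full loss + gradient for one sequence, accumulated into g
static double seq_nll_grad(const Params& q, const uvec& seq, const uvec& tags,
                           const mat& allowed, const mat& tre,
                           const mat* drop, Grads& g) {
  SeqForward sf;
  seq_forward(q, seq, drop, sf);
  mat dEmis;
  double nll = crf_nll_grad(sf.Emis, tre, allowed, tags, dEmis, g.Tr);
  // projection
  g.Wp += dEmis * sf.Hcat.t();
  g.bp += sum(dEmis, 1);
  mat dH = q.Wp.t() * dEmis;          // 2H x T
  if (drop != nullptr) dH %= sf.Drop; // Hcat already carries the mask
  int H = q.H, T = seq.n_elem;
  mat dHf = dH.rows(0, H - 1);
  mat dHb = fliplr(mat(dH.rows(H, 2 * H - 1)));
  mat dX = lstm_backward(q.Wf, q.Uf, sf.fwd, sf.X, dHf, g.Wf, g.Uf, g.bf);
  mat Xr = fliplr(sf.X);
  mat dXr = lstm_backward(q.Wb, q.Ub, sf.bwd, Xr, dHb, g.Wb, g.Ub, g.bb);
  dX += fliplr(dXr);
  for (int t = 0; t < T; ++t) g.E.col(seq[t]) += dX.col(t);
  return nll;
}

static void adam_update(mat& p, mat& m, mat& v, const mat& g,
                        double lr, double b1, double b2, double eps,
                        double t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  mat mh = m / (1 - std::pow(b1, t));
  mat vh = v / (1 - std::pow(b2, t));
  p -= lr * mh / (sqrt(vh) + eps);
}

static void adam_update_vec(vec& p, vec& m, vec& v, const vec& g,
                            double lr, double b1, double b2, double eps,
                            double t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  vec mh = m / (1 - std::pow(b1, t));
  vec vh = v / (1 - std::pow(b2, t));
  p -= lr * mh / (sqrt(vh) + eps);
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_epoch(Rcpp::List params, Rcpp::List adam,
                         Rcpp::List seqs, Rcpp::List tags,
                         arma::mat allowed, double dropout, double lr,
                         int batch_size, int seed) {
  Params q = unpack(params);
  int n = seqs.size();
  std::vector<uvec> xs(n), ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = Rcpp::as<uvec>(seqs[i]);
    ys[i] = Rcpp::as<uvec>(tags[i]);
  }
  std::mt19937 gen(seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), gen);
  std::bernoulli_distribution keep(1.0 - dropout);

  // Adam state
  mat mE = Rcpp::as<mat>(adam["mE"]), vE = Rcpp::as<mat>(adam["vE"]);
  mat mWf = Rcpp::as<mat>(adam["mWf"]), vWf = Rcpp::as<mat>(adam["vWf"]);
  mat mUf = Rcpp::as<mat>(adam["mUf"]), vUf = Rcpp::as<mat>(adam["vUf"]);
  vec mbf = Rcpp::as<vec>(adam["mbf"]), vbf = Rcpp::as<vec>(adam["vbf"]);
  mat mWb = Rcpp::as<mat>(adam["mWb"]), vWb = Rcpp::as<mat>(adam["vWb"]);
  mat mUb = Rcpp::as<mat>(adam["mUb"]), vUb = Rcpp::as<mat>(adam["vUb"]);
  vec mbb = Rcpp::as<vec>(adam["mbb"]), vbb = Rcpp::as<vec>(adam["vbb"]);
  mat mWp = Rcpp::as<mat>(adam["mWp"]), vWp = Rcpp::as<mat>(adam["vWp"]);
  vec mbp = Rcpp::as<vec>(adam["mbp"]), vbp = Rcpp::as<vec>(adam["vbp"]);
  mat mTr = Rcpp::as<mat>(adam["mTr"]), vTr = Rcpp::as<mat>(adam["vTr"]);
  double step = Rcpp::as<double>(adam["step"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  Grads g;
  g.zero(q);
  double total_nll = 0.0;
  int in_batch = 0;
  auto apply = [&](int count) {
    if (count == 0) return;
    double c = 1.0 / count;
    step += 1.0;
    adam_update(q.E, mE, vE, g.E * c, lr, b1, b2, eps, step);
    adam_update(q.Wf, mWf, vWf, g.Wf * c, lr, b1, b2, eps, step);
    adam_update(q.Uf, mUf, vUf, g.Uf * c, lr, b1, b2, eps, step);
    adam_update_vec(q.bf, mbf, vbf, g.bf * c, lr, b1, b2, eps, step);
    adam_update(q.Wb, mWb, vWb, g.Wb * c, lr, b1, b2, eps, step);
    adam_update(q.Ub, mUb, vUb, g.Ub * c, lr, b1, b2, eps, step);
    adam_update_vec(q.bb, mbb, vbb, g.bb * c, lr, b1, b2, eps, step);
    adam_update(q.Wp, mWp, vWp, g.Wp * c, lr, b1, b2, eps, step);
    adam_update_vec(q.bp, mbp, vbp, g.bp * c, lr, b1, b2, eps, step);
    adam_update(q.Tr, mTr, vTr, g.Tr * c, lr, b1, b2, eps, step);
    g.zero(q);
  };
  for (int idx = 0; idx < n; ++idx) {
    const uvec& s = xs[order[idx]];
    const uvec& y = ys[order[idx]];
    if (s.n_elem == 0) continue;
    mat tre = effective_transitions(q, allowed);
    mat drop;
    mat* dropp = nullptr;
    if (dropout > 0) {
      drop.set_size(2 * q.H, s.n_elem);
      for (uword j = 0; j < drop.n_elem; ++j) {
        drop(j) = keep(gen) ? 1.0 / (1.0 - dropout) : 0.0;
      }
      dropp = &drop;
    }
    total_nll += seq_nll_grad(q, s, y, allowed, tre, dropp, g);
    if (++in_batch == batch_size) {
      apply(in_batch);
      in_batch = 0;
    }
  }
  apply(in_batch);

  Rcpp::List adam_out = Rcpp::List::create(
      Rcpp::Named("mE") = mE, Rcpp::Named("vE") = vE,
      Rcpp::Named("mWf") = mWf, Rcpp::Named("vWf") = vWf,
      Rcpp::Named("mUf") = mUf, Rcpp::Named("vUf") = vUf,
      Rcpp::Named("mbf") = mbf, Rcpp::Named("vbf") = vbf,
      Rcpp::Named("mWb") = mWb, Rcpp::Named("vWb") = vWb,
      Rcpp::Named("mUb") = mUb, Rcpp::Named("vUb") = vUb,
      Rcpp::Named("mbb") = mbb, Rcpp::Named("vbb") = vbb,
      Rcpp::Named("mWp") = mWp, Rcpp::Named("vWp") = vWp,
      Rcpp::Named("mbp") = mbp, Rcpp::Named("vbp") = vbp,
      Rcpp::Named("mTr") = mTr, Rcpp::Named("vTr") = vTr,
      Rcpp::Named("step") = step);
  return Rcpp::List::create(Rcpp::Named("params") = pack(q),
                            Rcpp::Named("adam") = adam_out,
                            Rcpp::Named("mean_nll") = total_nll / n);
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_nll_grad(Rcpp::List params, Rcpp::IntegerVector seq,
                            Rcpp::IntegerVector tags, arma::mat allowed) {
  Params q = unpack(params);
  uvec s = Rcpp::as<uvec>(seq), y = Rcpp::as<uvec>(tags);
  Grads g;
  g.zero(q);
  mat tre = effective_transitions(q, allowed);
  double nll = seq_nll_grad(q, s, y, allowed, tre, nullptr, g);
  return Rcpp::List::create(
      Rcpp::Named("nll") = nll,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("E") = g.E, Rcpp::Named("Wf") = g.Wf,
          Rcpp::Named("Uf") = g.Uf, Rcpp::Named("bf") = g.bf,
          Rcpp::Named("Wb") = g.Wb, Rcpp::Named("Ub") = g.Ub,
          Rcpp::Named("bb") = g.bb, Rcpp::Named("Wp") = g.Wp,
          Rcpp::Named("bp") = g.bp, Rcpp::Named("Tr") = g.Tr));
}

// [[Rcpp::export]]
double cpp_crf_nll(Rcpp::List params, Rcpp::IntegerVector seq,
                   Rcpp::IntegerVector tags, arma::mat allowed) {
  Params q = unpack(params);
  uvec s = Rcpp::as<uvec>(seq), y = Rcpp::as<uvec>(tags);
  SeqForward sf;
  seq_forward(q, s, nullptr, sf);
  mat tre = effective_transitions(q, allowed);
  mat dEmis, dTr(q.K + 2, q.K + 2, fill::zeros);
  return crf_nll_grad(sf.Emis, tre, allowed, y, dEmis, dTr);
}

// [[Rcpp::export]]
arma::mat cpp_crf_emissions(Rcpp::List params, Rcpp::IntegerVector seq) {
  Params q = unpack(params);
  uvec s = Rcpp::as<uvec>(seq);
  SeqForward sf;
  seq_forward(q, s, nullptr, sf);
  return sf.Emis.t(); // T x K, matching the R-side convention
}

// Viterbi with ties broken toward the lowest tag index
static uvec viterbi(const mat& emis, const mat& tre) {
  int K = emis.n_rows, T = emis.n_cols;
  int START = K, STOP = K + 1;
  mat delta(K, T);
  umat psi(K, T, fill::zeros);
  delta.col(0) = tre.submat(START, 0, START, K - 1).t() + emis.col(0);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = -datum::inf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(i, t - 1) + tre(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + emis(j, t);
      psi(j, t) = arg;
    }
  }
  vec fin = delta.col(T - 1) + tre.submat(0, STOP, K - 1, STOP);
  uvec path(T);
  path[T - 1] = fin.index_max();
  for (int t = T - 1; t >= 1; --t) path[t - 1] = psi(path[t], t);
  return path;
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_decode(Rcpp::List params, Rcpp::List seqs,
                          arma::mat allowed) {
  Params q = unpack(params);
  mat tre = effective_transitions(q, allowed);
  int n = seqs.size();
  Rcpp::List out(n);
  for (int i = 0; i < n; ++i) {
    uvec s = Rcpp::as<uvec>(seqs[i]);
    if (s.n_elem == 0) {
      out[i] = Rcpp::IntegerVector(0);
      continue;
    }
    SeqForward sf;
    seq_forward(q, s, nullptr, sf);
    uvec path = viterbi(sf.Emis, tre);
    out[i] = Rcpp::IntegerVector(path.begin(), path.end());
  }
  return out;
}
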