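// LSTM policy core: teacher-forced forward (sequence log-likelihoods),
// backpropagation through time, and autoregressive sampling.
//
// The R level owns parameter containers, the optimizer and all chemistry;
// these routines only run the dense math. Gate layout in the fused weight
// matrices is (input, forget, cell, output), matching the R initializer.
// Sampling consumes R's RNG stream (unif_rand), so set.seed() reproduces
// runs exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct Net {
  arma::mat emb;                 // V x E
  std::vector<arma::mat> Wx;     // 4H x in
  std::vector<arma::mat> Wh;     // 4H x H
  std::vector<arma::rowvec> b;   // 4H
  arma::mat Wo;                  // V x H
  arma::rowvec bo;               // V
  int L;
};

Net unpack(const List& params) {
  Net net;
  net.emb = as<arma::mat>(params["emb"]);
  List layers = params["layers"];
  net.L = layers.size();
  for (int l = 0; l < net.L; ++l) {
    List ly = layers[l];
    net.Wx.push_back(as<arma::mat>(ly["Wx"]));
    net.Wh.push_back(as<arma::mat>(ly["Wh"]));
    net.b.push_back(as<arma::rowvec>(ly["b"]));
  }
  net.Wo = as<arma::mat>(params["Wo"]);
  net.bo = as<arma::rowvec>(params["bo"]);
  return net;
}

inline arma::mat row_softmax_masked(arma::mat logits, int pad0, int start0) {
  logits.col(pad0).fill(-1e30);
  logits.col(start0).fill(-1e30);
  arma::vec m = arma::max(logits, 1);
  logits.each_col() -= m;
  arma::mat e = arma::exp(logits);
  arma::vec s = arma::sum(e, 1);
  e.each_col() /= s;
  return e;
}

}  // namespace

// Teacher-forced forward over a padded batch, with optional BPTT.
// inp/tgt are B x T 1-based token matrices; lens gives per-sequence length
// (positions t <= lens[b] are active). Two backward modes:
//   - `weights` of length B: gradients of sum_b weights[b] * loglik_b;
//   - `targets` of length B: gradients of the squared-difference loss
//     mean_b (targets_b - loglik_b)^2, with the per-sequence weights
//     derived from the forward loglik in the same pass.
// [[Rcpp::export(name = ".cpp_policy_fb")]]
List cpp_policy_fb(List params, IntegerMatrix inp_, IntegerMatrix tgt_,
                   IntegerVector lens_, NumericVector weights,
                   NumericVector targets,
                   int pad, int start_tok, bool want_probs) {
  Net net = unpack(params);
  const int B = inp_.nrow(), T = inp_.ncol(), L = net.L;
  const int V = net.emb.n_rows;
  const int pad0 = pad - 1, start0 = start_tok - 1;
  const bool target_mode = targets.size() == B;
  const bool backward = weights.size() == B || target_mode;

  arma::imat inp(B, T), tgt(B, T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      inp(b, t) = inp_(b, t) - 1;
      tgt(b, t) = tgt_(b, t) - 1;
    }
  }
  arma::ivec lens(B);
  for (int b = 0; b < B; ++b) lens[b] = lens_[b];

  std::vector<int> H(L);
  for (int l = 0; l < L; ++l) H[l] = net.Wh[l].n_cols;

  // per-layer, per-step caches for backward
  std::vector<std::vector<arma::mat>> cX, cI, cF, cG, cO, cTC, cCP, cHP;
  if (backward) {
    cX.assign(L, std::vector<arma::mat>(T));
    cI = cF = cG = cO = cTC = cCP = cHP = cX;
  }
  std::vector<arma::mat> Ps(T);

  std::vector<arma::mat> h(L), c(L);
  for (int l = 0; l < L; ++l) {
    h[l].zeros(B, H[l]);
    c[l].zeros(B, H[l]);
  }

  arma::vec loglik(B, arma::fill::zeros);
  List probs_out;

  for (int t = 0; t < T; ++t) {
    arma::mat x(B, net.emb.n_cols);
    for (int b = 0; b < B; ++b) x.row(b) = net.emb.row(inp(b, t));
    for (int l = 0; l < L; ++l) {
      const int Hl = H[l];
      arma::mat Z = x * net.Wx[l].t() + h[l] * net.Wh[l].t();
      Z.each_row() += net.b[l];
      arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.cols(0, Hl - 1)));
      arma::mat gf = 1.0 / (1.0 + arma::exp(-Z.cols(Hl, 2 * Hl - 1)));
      arma::mat gg = arma::tanh(Z.cols(2 * Hl, 3 * Hl - 1));
      arma::mat go = 1.0 / (1.0 + arma::exp(-Z.cols(3 * Hl, 4 * Hl - 1)));
      arma::mat cc = gf % c[l] + gi % gg;
      arma::mat tc = arma::tanh(cc);
      if (backward) {
        cX[l][t] = x; cI[l][t] = gi; cF[l][t] = gf; cG[l][t] = gg;
        cO[l][t] = go; cTC[l][t] = tc; cCP[l][t] = c[l]; cHP[l][t] = h[l];
      }
      c[l] = cc;
      h[l] = go % tc;
      x = h[l];
    }
    arma::mat logits = x * net.Wo.t();
    logits.each_row() += net.bo;
    arma::mat P = row_softmax_masked(logits, pad0, start0);
    for (int b = 0; b < B; ++b) {
      if (t < lens[b]) {
        double p = P(b, tgt(b, t));
        loglik[b] += std::log(std::max(p, 1e-30));
      }
    }
    if (backward || want_probs) Ps[t] = P;
  }

  if (want_probs) {
    probs_out = List(T);
    for (int t = 0; t < T; ++t) probs_out[t] = Ps[t];
  }

  List out = List::create(_["loglik"] = loglik);
  if (want_probs) out["probs"] = probs_out;
  if (!backward) return out;

  arma::vec w(B);
  if (target_mode) {
    // dLoss/dloglik for mean_b (targets_b - loglik_b)^2
    for (int b = 0; b < B; ++b) {
      w[b] = -2.0 / B * (targets[b] - loglik[b]);
    }
    double loss = 0.0;
    for (int b = 0; b < B; ++b) {
      loss += std::pow(targets[b] - loglik[b], 2.0);
    }
    out["loss"] = loss / B;
  } else {
    for (int b = 0; b < B; ++b) w[b] = weights[b];
  }

  // ---- backward -----------------------------------------------------------
  arma::mat gEmb(net.emb.n_rows, net.emb.n_cols, arma::fill::zeros);
  std::vector<arma::mat> gWx(L), gWh(L);
  std::vector<arma::rowvec> gb(L);
  for (int l = 0; l < L; ++l) {
    gWx[l].zeros(arma::size(net.Wx[l]));
    gWh[l].zeros(arma::size(net.Wh[l]));
    gb[l].zeros(4 * H[l]);
  }
  arma::mat gWo(arma::size(net.Wo), arma::fill::zeros);
  arma::rowvec gbo(V, arma::fill::zeros);

  std::vector<arma::mat> dh_t(L), dc_t(L);
  for (int l = 0; l < L; ++l) {
    dh_t[l].zeros(B, H[l]);
    dc_t[l].zeros(B, H[l]);
  }

  for (int t = T - 1; t >= 0; --t) {
    arma::mat dlog = -Ps[t];
    for (int b = 0; b < B; ++b) dlog(b, tgt(b, t)) += 1.0;
    for (int b = 0; b < B; ++b) {
      dlog.row(b) *= (t < lens[b]) ? w[b] : 0.0;
    }
    const arma::mat& htop = (L > 0) ? (cO[L - 1][t] % cTC[L - 1][t])
                                    : cX[0][t];
    gWo += dlog.t() * htop;
    gbo += arma::sum(dlog, 0);
    arma::mat dh = dlog * net.Wo;
    for (int l = L - 1; l >= 0; --l) {
      const int Hl = H[l];
      arma::mat dh_l = dh + dh_t[l];
      arma::mat dcc = dh_l % cO[l][t] % (1.0 - arma::square(cTC[l][t]))
                      + dc_t[l];
      arma::mat d_o = dh_l % cTC[l][t];
      arma::mat d_i = dcc % cG[l][t];
      arma::mat d_g = dcc % cI[l][t];
      arma::mat d_f = dcc % cCP[l][t];
      dc_t[l] = dcc % cF[l][t];
      arma::mat dZ(B, 4 * Hl);
      dZ.cols(0, Hl - 1) = d_i % cI[l][t] % (1.0 - cI[l][t]);
      dZ.cols(Hl, 2 * Hl - 1) = d_f % cF[l][t] % (1.0 - cF[l][t]);
      dZ.cols(2 * Hl, 3 * Hl - 1) = d_g % (1.0 - arma::square(cG[l][t]));
      dZ.cols(3 * Hl, 4 * Hl - 1) = d_o % cO[l][t] % (1.0 - cO[l][t]);
      gWx[l] += dZ.t() * cX[l][t];
      gWh[l] += dZ.t() * cHP[l][t];
      gb[l] += arma::sum(dZ, 0);
      dh_t[l] = dZ * net.Wh[l];
      dh = dZ * net.Wx[l];
    }
    for (int b = 0; b < B; ++b) gEmb.row(inp(b, t)) += dh.row(b);
  }

  List gLayers(L);
  for (int l = 0; l < L; ++l) {
    gLayers[l] = List::create(_["Wx"] = gWx[l], _["Wh"] = gWh[l],
                              _["b"] = NumericVector(gb[l].begin(),
                                                     gb[l].end()));
  }
  out["grads"] = List::create(
      _["emb"] = gEmb, _["layers"] = gLayers, _["Wo"] = gWo,
      _["bo"] = NumericVector(gbo.begin(), gbo.end()));
  return out;
}

// Autoregressive multinomial sampling. Returns per-sequence token vectors
// (1-based, terminated by the end token where reached) and exact NLLs.
// [[Rcpp::export(name = ".cpp_policy_sample")]]
List cpp_policy_sample(List params, int B, int max_length, int pad,
                       int start_tok, int end_tok) {
  Net net = unpack(params);
  const int L = net.L, V = net.emb.n_rows;
  const int pad0 = pad - 1, start0 = start_tok - 1, end0 = end_tok - 1;

  std::vector<int> H(L);
  for (int l = 0; l < L; ++l) H[l] = net.Wh[l].n_cols;
  std::vector<arma::mat> h(L), c(L);
  for (int l = 0; l < L; ++l) {
    h[l].zeros(B, H[l]);
    c[l].zeros(B, H[l]);
  }

  std::vector<std::vector<int>> toks(B);
  std::vector<bool> alive(B, true);
  arma::vec nll(B, arma::fill::zeros);
  std::vector<int> prev(B, start0);
  int n_alive = B;

  RNGScope rng;
  for (int t = 0; t < max_length && n_alive > 0; ++t) {
    arma::mat x(B, net.emb.n_cols);
    for (int b = 0; b < B; ++b) x.row(b) = net.emb.row(prev[b]);
    for (int l = 0; l < L; ++l) {
      const int Hl = H[l];
      arma::mat Z = x * net.Wx[l].t() + h[l] * net.Wh[l].t();
      Z.each_row() += net.b[l];
      arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.cols(0, Hl - 1)));
      arma::mat gf = 1.0 / (1.0 + arma::exp(-Z.cols(Hl, 2 * Hl - 1)));
      arma::mat gg = arma::tanh(Z.cols(2 * Hl, 3 * Hl - 1));
      arma::mat go = 1.0 / (1.0 + arma::exp(-Z.cols(3 * Hl, 4 * Hl - 1)));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % arma::tanh(c[l]);
      x = h[l];
    }
    arma::mat logits = x * net.Wo.t();
    logits.each_row() += net.bo;
    arma::mat P = row_softmax_masked(logits, pad0, start0);
    for (int b = 0; b < B; ++b) {
      if (!alive[b]) continue;
      const double u = unif_rand();
      double acc = 0.0;
      int k = V - 1;
      for (int j = 0; j < V; ++j) {
        acc += P(b, j);
        if (u <= acc) { k = j; break; }
      }
      prev[b] = k;
      toks[b].push_back(k + 1);
      nll[b] -= std::log(std::max(P(b, k), 1e-30));
      if (k == end0) { alive[b] = false; --n_alive; }
    }
  }

  List tok_out(B);
  for (int b = 0; b < B; ++b) tok_out[b] = IntegerVector(toks[b].begin(),
                                                         toks[b].end());
  return List::create(_["tokens"] = tok_out,
                      _["nll"] = NumericVector(nll.begin(), nll.end()));
}
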