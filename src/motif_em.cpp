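#include <Rcpp.h>
using namespace Rcpp;

// One E-step of the zero-or-one-occurrence motif mixture model.
//
// Per sequence the latent state is either "background only" (prior pi0) or
// (motif k, start p, strand s) with prior pi_k / (2 * npos_k). A placement's
// log-likelihood replaces the background emission of the motif window by the
// PWM column probabilities; everything outside the window keeps the order-1
// Markov background likelihood, which cancels in the posterior except for
// the window term.
//
// seqs: list of integer vectors coded 0..3
// bgl:  list of numeric vectors, per-position background log-probability
// pwms: list of L_k x 4 matrices of column log-probabilities
// logpi: length K+1, [0] = log pi0, then log pi_k
//
// Returns observed-data log-likelihood, per-motif expected occupancy,
// expected base counts per motif column, flank base counts for motif
// extension, per-sequence per-motif posterior, and the best placement per
// sequence.
// [[Rcpp::export]]
List motif_estep_cpp(List seqs, List bgl, List pwms, NumericVector logpi,
                     bool accumulate) {
  const int n = seqs.size();
  const int K = pwms.size();

  // flatten PWMs: P[k][l*4 + b]; Prc is the reverse complement so the
  // minus-strand window score is a forward scan of Prc
  std::vector<std::vector<double> > P(K), Prc(K);
  std::vector<int> Lk(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix m = as<NumericMatrix>(pwms[k]);
    const int L = m.nrow();
    Lk[k] = L;
    P[k].resize(L * 4);
    Prc[k].resize(L * 4);
    for (int l = 0; l < L; ++l)
      for (int b = 0; b < 4; ++b) {
        P[k][l * 4 + b] = m(l, b);
        Prc[k][l * 4 + b] = m(L - 1 - l, 3 - b);
      }
  }

  std::vector<NumericMatrix> counts(K);
  NumericMatrix flankL(K, 4), flankR(K, 4);
  NumericVector flankLw(K), flankRw(K);
  if (accumulate)
    for (int k = 0; k < K; ++k) counts[k] = NumericMatrix(Lk[k], 4);

  NumericVector occ(K);
  NumericMatrix post(n, K + 1);
  IntegerVector best_k(n), best_pos(n), best_strand(n);
  NumericVector best_gamma(n);
  double loglik = 0.0;

  std::vector<double> w, pre;
  std::vector<int> cand_k, cand_p, cand_s;

  for (int i = 0; i < n; ++i) {
    IntegerVector sv = seqs[i];
    NumericVector bl = bgl[i];
    const int* s = INTEGER(sv);
    const double* blp = REAL(bl);
    const int len = sv.size();

    // background prefix sums: pre[j] = sum of bl[0..j-1]
    pre.resize(len + 1);
    pre[0] = 0.0;
    for (int j = 0; j < len; ++j) pre[j + 1] = pre[j] + blp[j];
    const double B = pre[len];

    w.clear(); cand_k.clear(); cand_p.clear(); cand_s.clear();
    w.push_back(logpi[0]);
    cand_k.push_back(-1); cand_p.push_back(-1); cand_s.push_back(-1);

    for (int k = 0; k < K; ++k) {
      const int L = Lk[k];
      const int npos = len - L + 1;
      if (npos <= 0) continue;
      const double prior = logpi[k + 1] - std::log(2.0 * npos);
      const double* pk = P[k].data();
      const double* prck = Prc[k].data();
      for (int p = 0; p < npos; ++p) {
        double dplus = 0.0, dminus = 0.0;
        const int* sp = s + p;
        for (int l = 0; l < L; ++l) {
          const int b4 = l * 4 + sp[l];
          dplus += pk[b4];
          dminus += prck[b4];
        }
        const double bgw = pre[p + L] - pre[p];
        w.push_back(prior + dplus - bgw);
        cand_k.push_back(k); cand_p.push_back(p); cand_s.push_back(0);
        w.push_back(prior + dminus - bgw);
        cand_k.push_back(k); cand_p.push_back(p); cand_s.push_back(1);
      }
    }

    // log-sum-exp normalization
    double mx = w[0];
    for (size_t c = 1; c < w.size(); ++c) if (w[c] > mx) mx = w[c];
    double Z = 0.0;
    for (size_t c = 0; c < w.size(); ++c) Z += std::exp(w[c] - mx);
    loglik += B + mx + std::log(Z);

    // per-motif totals and best placement
    std::vector<double> gk(K, 0.0), gbest(K, -1.0);
    std::vector<int> gbest_p(K, -1), gbest_s(K, 0);
    post(i, 0) = std::exp(w[0] - mx) / Z;
    for (size_t c = 1; c < w.size(); ++c) {
      const double g = std::exp(w[c] - mx) / Z;
      if (g < 1e-14) continue;
      const int k = cand_k[c];
      gk[k] += g;
      if (g > gbest[k]) { gbest[k] = g; gbest_p[k] = cand_p[c];
                          gbest_s[k] = cand_s[c]; }
      if (accumulate) {
        const int L = Lk[k], p = cand_p[c];
        NumericMatrix& C = counts[k];
        // flank (extension) evidence comes from confident placements
        // only, so ambiguous cross-motif matches cannot steer growth
        const bool conf = g > 0.5;
        if (cand_s[c] == 0) {
          for (int l = 0; l < L; ++l) C(l, s[p + l]) += g;
          if (conf && p - 1 >= 0) { flankL(k, s[p - 1]) += g;
                                    flankLw[k] += g; }
          if (conf && p + L < len) { flankR(k, s[p + L]) += g;
                                     flankRw[k] += g; }
        } else {
          for (int l = 0; l < L; ++l) C(L - 1 - l, 3 - s[p + l]) += g;
          // motif-left flank on minus strand sits right of the window
          if (conf && p + L < len) { flankL(k, 3 - s[p + L]) += g;
                                     flankLw[k] += g; }
          if (conf && p - 1 >= 0) { flankR(k, 3 - s[p - 1]) += g;
                                    flankRw[k] += g; }
        }
      }
    }
    int bk = -1; double bg_ = -1.0;
    for (int k = 0; k < K; ++k) {
      post(i, k + 1) = gk[k];
      occ[k] += gk[k];
      if (gk[k] > bg_) { bg_ = gk[k]; bk = k; }
    }
    if (bk >= 0) {
      best_k[i] = bk + 1;
      best_pos[i] = gbest_p[bk];
      best_strand[i] = gbest_s[bk];
      best_gamma[i] = bg_;
    } else {
      best_k[i] = 0; best_pos[i] = -1; best_strand[i] = -1;
      best_gamma[i] = 0.0;
    }
  }

  List cl(K);
  if (accumulate) for (int k = 0; k < K; ++k) cl[k] = counts[k];
  return List::create(_["loglik"] = loglik,
                      _["occ"] = occ,
                      _["counts"] = cl,
                      _["flankL"] = flankL, _["flankR"] = flankR,
                      _["flankLw"] = flankLw, _["flankRw"] = flankRw,
                      _["post"] = post,
                      _["best_k"] = best_k,
                      _["best_pos"] = best_pos,
                      _["best_strand"] = best_strand,
                      _["best_gamma"] = best_gamma);
}
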