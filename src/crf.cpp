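// Linear-chain CRF inner loops: penalized negative log-likelihood with
// analytic gradient (forward-backward) and Viterbi decoding.
//
// Parameter layout in `par` (length nfeat*L + L*L + 2L):
//   [0, nfeat*L)            state weights, column-major: w(f, y) = par[f + y*nfeat]
//   [nfeat*L, nfeat*L+L*L)  transitions: t(y_prev, y) = par[off + y_prev + y*L]
//   then L start weights and L end weights.
// Feature indices arrive 1-based from R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// emission scores for one sentence: T x L (column-major)
static void emissions(const List& sent_feats, const double* par, int nfeat,
                      int L, std::vector<double>& emit, int T) {
  std::fill(emit.begin(), emit.end(), 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector fs = sent_feats[t];
    for (int y = 0; y < L; ++y) {
      double s = 0.0;
      const double* wy = par + (size_t)y * nfeat;
      for (int k = 0; k < fs.size(); ++k) s += wy[fs[k] - 1];
      emit[t + (size_t)y * T] = s;
    }
  }
}

// [[Rcpp::export(name = ".crf_negll_grad")]]
List crf_negll_grad(NumericVector par, List feats, List labels, int nfeat,
                    int L, double l2) {
  const double* p = par.begin();
  const double* trans = p + (size_t)nfeat * L;
  const double* wstart = trans + (size_t)L * L;
  const double* wend = wstart + L;
  NumericVector grad(par.size());
  double* g = grad.begin();
  double* gtrans = g + (size_t)nfeat * L;
  double* gstart = gtrans + (size_t)L * L;
  double* gend = gstart + L;
  double negll = 0.0;
  int nsent = feats.size();
  std::vector<double> tmp(L);

  for (int s = 0; s < nsent; ++s) {
    List sent_feats = feats[s];
    IntegerVector lab = labels[s];
    int T = sent_feats.size();
    if (T == 0) continue;
    std::vector<double> emit((size_t)T * L);
    emissions(sent_feats, p, nfeat, L, emit, T);

    // forward (log alpha), backward (log beta)
    std::vector<double> la((size_t)T * L), lb((size_t)T * L);
    for (int y = 0; y < L; ++y) la[0 + (size_t)y * T] = wstart[y] + emit[0 + (size_t)y * T];
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp)
          tmp[yp] = la[(t - 1) + (size_t)yp * T] + trans[yp + (size_t)y * L];
        la[t + (size_t)y * T] = logsumexp(tmp) + emit[t + (size_t)y * T];
      }
    }
    for (int y = 0; y < L; ++y) lb[(T - 1) + (size_t)y * T] = wend[y];
    for (int t = T - 2; t >= 0; --t) {
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn)
          tmp[yn] = trans[y + (size_t)yn * L] + emit[(t + 1) + (size_t)yn * T] +
                    lb[(t + 1) + (size_t)yn * T];
        lb[t + (size_t)y * T] = logsumexp(tmp);
      }
    }
    for (int y = 0; y < L; ++y)
      tmp[y] = la[(T - 1) + (size_t)y * T] + wend[y];
    double logZ = logsumexp(tmp);

    // gold path score
    double gold = wstart[lab[0] - 1];
    for (int t = 0; t < T; ++t) {
      gold += emit[t + (size_t)(lab[t] - 1) * T];
      if (t > 0) gold += trans[(lab[t - 1] - 1) + (size_t)(lab[t] - 1) * L];
    }
    gold += wend[lab[T - 1] - 1];
    negll += logZ - gold;

    // expected counts minus observed counts
    for (int t = 0; t < T; ++t) {
      IntegerVector fs = sent_feats[t];
      for (int y = 0; y < L; ++y) {
        double lp = la[t + (size_t)y * T] + lb[t + (size_t)y * T] - logZ;
        double pr = std::exp(lp);
        double* gy = g + (size_t)y * nfeat;
        for (int k = 0; k < fs.size(); ++k) gy[fs[k] - 1] += pr;
        if (t == 0) gstart[y] += pr;
        if (t == T - 1) gend[y] += pr;
      }
      int yg = lab[t] - 1;
      double* gy = g + (size_t)yg * nfeat;
      for (int k = 0; k < fs.size(); ++k) gy[fs[k] - 1] -= 1.0;
    }
    gstart[lab[0] - 1] -= 1.0;
    gend[lab[T - 1] - 1] -= 1.0;
    for (int t = 1; t < T; ++t) {
      for (int yp = 0; yp < L; ++yp) {
        double a = la[(t - 1) + (size_t)yp * T];
        for (int y = 0; y < L; ++y) {
          double lp = a + trans[yp + (size_t)y * L] + emit[t + (size_t)y * T] +
                      lb[t + (size_t)y * T] - logZ;
          gtrans[yp + (size_t)y * L] += std::exp(lp);
        }
      }
      gtrans[(lab[t - 1] - 1) + (size_t)(lab[t] - 1) * L] -= 1.0;
    }
  }

  // L2 penalty
  double pen = 0.0;
  for (R_xlen_t i = 0; i < par.size(); ++i) {
    pen += p[i] * p[i];
    g[i] += l2 * p[i];
  }
  negll += 0.5 * l2 * pen;
  return List::create(Named("value") = negll, Named("grad") = grad);
}

// [[Rcpp::export(name = ".crf_viterbi")]]
List crf_viterbi(NumericVector par, List feats, int nfeat, int L) {
  const double* p = par.begin();
  const double* trans = p + (size_t)nfeat * L;
  const double* wstart = trans + (size_t)L * L;
  const double* wend = wstart + L;
  int nsent = feats.size();
  List out(nsent);
  for (int s = 0; s < nsent; ++s) {
    List sent_feats = feats[s];
    int T = sent_feats.size();
    if (T == 0) { out[s] = IntegerVector(0); continue; }
    std::vector<double> emit((size_t)T * L);
    emissions(sent_feats, p, nfeat, L, emit, T);
    std::vector<double> delta((size_t)T * L);
    std::vector<int> psi((size_t)T * L);
    for (int y = 0; y < L; ++y) delta[0 + (size_t)y * T] = wstart[y] + emit[0 + (size_t)y * T];
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        double best = -1e300; int arg = 0;
        for (int yp = 0; yp < L; ++yp) {
          double v = delta[(t - 1) + (size_t)yp * T] + trans[yp + (size_t)y * L];
          if (v > best) { best = v; arg = yp; }
        }
        delta[t + (size_t)y * T] = best + emit[t + (size_t)y * T];
        psi[t + (size_t)y * T] = arg;
      }
    }
    double best = -1e300; int arg = 0;
    for (int y = 0; y < L; ++y) {
      double v = delta[(T - 1) + (size_t)y * T] + wend[y];
      if (v > best) { best = v; arg = y; }
    }
    IntegerVector path(T);
    path[T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = psi[t + (size_t)arg * T];
      path[t - 1] = arg + 1;
    }
    out[s] = path;
  }
  return out;
}
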