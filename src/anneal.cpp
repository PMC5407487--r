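#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Periodicity objective for one permutation.
// Xc: admissible spatial rows, centered (row mean removed); ss: row sums
// of squares; perm: 0-based column order; AT[t] = target autocorrelation
// at lag lags[t].  g = sum_i sum_t (A_i(lags[t]; perm) - AT[t])^2 with
// A_i the circular, mean-removed, variance-normalized autocorrelation of
// row i under the ordering.
static double g_of(const NumericMatrix &Xc, const NumericVector &ss,
                   const int *perm, const IntegerVector &lags,
                   const NumericVector &AT) {
  const int N = Xc.nrow(), M = Xc.ncol(), K = lags.size();
  double g = 0.0;
  for (int i = 0; i < N; ++i) {
    const double inv = 1.0 / ss[i];
    for (int t = 0; t < K; ++t) {
      const int k = lags[t];
      double num = 0.0;
      for (int j = 0; j < M; ++j) {
        int j2 = j + k;
        if (j2 >= M) j2 -= M;
        num += Xc(i, perm[j]) * Xc(i, perm[j2]);
      }
      const double d = num * inv - AT[t];
      g += d * d;
    }
  }
  return g;
}

// [[Rcpp::export]]
double g_value_cpp(NumericMatrix Xc, NumericVector ss, IntegerVector perm,
                   IntegerVector lags, NumericVector AT) {
  return g_of(Xc, ss, perm.begin(), lags, AT);
}

// Evaluate g for each row of a matrix of permutations (0-based).
// [[Rcpp::export]]
NumericVector g_value_many_cpp(NumericMatrix Xc, NumericVector ss,
                               IntegerMatrix perms, IntegerVector lags,
                               NumericVector AT) {
  const int P = perms.nrow(), M = perms.ncol();
  NumericVector out(P);
  std::vector<int> perm(M);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < M; ++j) perm[j] = perms(p, j);
    out[p] = g_of(Xc, ss, perm.data(), lags, AT);
  }
  return out;
}

// One Metropolis annealing chain over permutations.
// proposal: 0 = swap-two, 1 = reverse-segment.  Uses R's RNG so the
// chain is reproducible under set.seed().  Trace rows record
// (iteration, current g, best g, temperature) every trace_every steps.
// [[Rcpp::export]]
List anneal_chain_cpp(NumericMatrix Xc, NumericVector ss,
                      IntegerVector lags, NumericVector AT,
                      IntegerVector perm0, int iterations, double t0,
                      double cooling, int proposal, int trace_every) {
  RNGScope scope;
  const int M = perm0.size();
  std::vector<int> cur(perm0.begin(), perm0.end());
  std::vector<int> best(cur), prop(cur);
  double gcur = g_of(Xc, ss, cur.data(), lags, AT);
  double gbest = gcur, T = t0;
  const int ntr = iterations / trace_every + 1;
  NumericMatrix trace(ntr, 4);
  int tr = 0, accepted = 0;
  trace(tr, 0) = 0; trace(tr, 1) = gcur; trace(tr, 2) = gbest;
  trace(tr, 3) = T; ++tr;
  for (int it = 1; it <= iterations; ++it) {
    int i = (int)(unif_rand() * M);
    int j = (int)(unif_rand() * M);
    while (j == i) j = (int)(unif_rand() * M);
    if (i > j) std::swap(i, j);
    prop = cur;
    if (proposal == 0)
      std::swap(prop[i], prop[j]);
    else
      std::reverse(prop.begin() + i, prop.begin() + j + 1);
    const double gp = g_of(Xc, ss, prop.data(), lags, AT);
    const double dg = gp - gcur;
    if (dg <= 0.0 || unif_rand() < std::exp(-dg / T)) {
      cur.swap(prop);
      gcur = gp;
      ++accepted;
      if (gcur < gbest) {
        gbest = gcur;
        best = cur;
      }
    }
    T *= cooling;
    if (it % trace_every == 0 && tr < ntr) {
      trace(tr, 0) = it; trace(tr, 1) = gcur; trace(tr, 2) = gbest;
      trace(tr, 3) = T; ++tr;
    }
  }
  return List::create(
      _["best_perm"] = IntegerVector(best.begin(), best.end()),
      _["best_g"] = gbest, _["final_g"] = gcur,
      _["accept_rate"] = (double)accepted / iterations,
      _["trace"] = trace);
}
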