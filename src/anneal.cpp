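#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Mismatch count between A(i,j) and its in-range grid neighbours
// A(i+1,j), A(i-1,j), A(i,j+1), A(i,j-1); 0-based indices.
// Out-of-range neighbour terms are omitted, not zero-padded.
static inline int mismatch_count(const IntegerMatrix &A, int i, int j, int N) {
  const int a = A(i, j);
  int c = 0;
  if (i + 1 < N) c += (a != A(i + 1, j));
  if (i - 1 >= 0) c += (a != A(i - 1, j));
  if (j + 1 < N) c += (a != A(i, j + 1));
  if (j - 1 >= 0) c += (a != A(i, j - 1));
  return c;
}

// [[Rcpp::export]]
double cpp_cost(const IntegerMatrix &A, const NumericVector &dpow) {
  const int N = A.nrow();
  double F = 0.0;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j)
      F += dpow[j - i] * mismatch_count(A, i, j, N);
  return F;
}

// Cost of the network under a permutation without materialising the
// permuted matrix: entry (i,j) of the permuted matrix is A(p[i], p[j]).
// [[Rcpp::export]]
double cpp_cost_perm(const IntegerMatrix &A, const IntegerVector &perm,
                     const NumericVector &dpow) {
  const int N = A.nrow();
  double F = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    const int pi = perm[i];
    const int pim = (i - 1 >= 0) ? perm[i - 1] : -1;
    const int pip = (i + 1 < N) ? perm[i + 1] : -1;
    for (int j = i + 1; j < N; ++j) {
      const int pj = perm[j];
      const int a = A(pi, pj);
      int c = 0;
      if (pip >= 0) c += (a != A(pip, pj));
      if (pim >= 0) c += (a != A(pim, pj));
      if (j + 1 < N) c += (a != A(pi, perm[j + 1]));
      c += (a != A(pi, perm[j - 1]));  // j-1 >= i >= 0 always in range
      F += dpow[j - i] * c;
    }
  }
  return F;
}

static void swap_rowcol(IntegerMatrix &A, int a, int b) {
  const int N = A.nrow();
  for (int k = 0; k < N; ++k) std::swap(A(a, k), A(b, k));
  for (int k = 0; k < N; ++k) std::swap(A(k, a), A(k, b));
}

// Sum of cost terms for all pairs (i<j) with i or j in the index band S.
// Only these terms can change when positions inside S are touched.
// By symmetry of A, the four neighbour comparisons of the pair
// {p, q} reduce to a single uniform expression over the contiguous
// columns p-1, p, p+1, which keeps the scan cache-friendly:
//   c(p,q) = [p+1<N](A.,p[q] != A.,p+1[q]) + [p>0](A.,p[q] != A.,p-1[q])
//          + [q+1<N](A.,p[q] != A.,p[q+1]) + [q>0](A.,p[q] != A.,p[q-1])
static double band_cost(const IntegerMatrix &A, const std::vector<int> &S,
                        const std::vector<char> &inS, const NumericVector &dpow) {
  const int N = A.nrow();
  const int *base = A.begin();
  const double *w = dpow.begin();
  double F = 0.0;
  for (size_t s = 0; s < S.size(); ++s) {
    const int p = S[s];
    const int *cp = base + (size_t)p * N;
    const int *cup = (p + 1 < N) ? base + (size_t)(p + 1) * N : nullptr;
    const int *cdn = (p > 0) ? base + (size_t)(p - 1) * N : nullptr;
    for (int q = 0; q < N; ++q) {
      if (q == p) continue;
      if (inS[q] && q < p) continue;  // pair already counted from the other end
      const int a = cp[q];
      int c = 0;
      if (cup) c += (a != cup[q]);
      if (cdn) c += (a != cdn[q]);
      if (q + 1 < N) c += (a != cp[q + 1]);
      if (q > 0) c += (a != cp[q - 1]);
      F += w[q > p ? q - p : p - q] * c;
    }
  }
  return F;
}

static void make_band(int a, int b, int N, std::vector<int> &S,
                      std::vector<char> &inS) {
  S.clear();
  std::fill(inS.begin(), inS.end(), 0);
  const int cand[6] = {a - 1, a, a + 1, b - 1, b, b + 1};
  for (int k = 0; k < 6; ++k) {
    const int p = cand[k];
    if (p >= 0 && p < N && !inS[p]) {
      inS[p] = 1;
      S.push_back(p);
    }
  }
}

// Exact cost change for swapping list positions a and b (0-based).
// A must be the association matrix in the *current* order; it is restored
// before returning.
// [[Rcpp::export]]
double cpp_delta_swap(IntegerMatrix A, int a, int b, const NumericVector &dpow) {
  const int N = A.nrow();
  std::vector<int> S;
  std::vector<char> inS(N, 0);
  make_band(a, b, N, S, inS);
  const double before = band_cost(A, S, inS, dpow);
  swap_rowcol(A, a, b);
  const double after = band_cost(A, S, inS, dpow);
  swap_rowcol(A, a, b);
  return after - before;
}

// Simulated annealing on list positions. A0 is the association matrix in
// the starting order; the returned perm maps list position -> row of A0
// (0-based). One Monte-Carlo step (MCS) = N attempted pair swaps; T drops
// by t_dec every steps_per_level MCS until T <= t_final; a zero-temperature
// polish then accepts only dF <= 0 moves until one full MCS yields no
// strict improvement (or max_polish_mcs is hit).
// [[Rcpp::export]]
List cpp_anneal(const IntegerMatrix &A0, const NumericVector &dpow,
                double t_init, double t_dec, int steps_per_level,
                double t_final, int seed, int max_polish_mcs) {
  const int N = A0.nrow();
  IntegerMatrix A = clone(A0);
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> upos(0, N - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> S;
  std::vector<char> inS(N, 0);

  double cost = cpp_cost(A, dpow);
  double best_running = cost;
  std::vector<double> trace;

  auto attempt = [&](double T, bool zero_temp) -> double {
    // one attempted swap; returns accepted dF (0 if rejected)
    int a = upos(rng), b = upos(rng);
    while (b == a) b = upos(rng);
    make_band(a, b, N, S, inS);
    const double before = band_cost(A, S, inS, dpow);
    swap_rowcol(A, a, b);
    const double dF = band_cost(A, S, inS, dpow) - before;
    bool accept;
    if (dF <= 0.0) {
      accept = true;
    } else if (zero_temp) {
      accept = false;
    } else {
      accept = unif(rng) < std::exp(-dF / T);
    }
    if (accept) {
      std::swap(perm[a], perm[b]);
      cost += dF;
      return dF;
    }
    swap_rowcol(A, a, b);  // revert
    return 0.0;
  };

  for (double T = t_init; T > t_final; T -= t_dec) {
    for (int s = 0; s < steps_per_level; ++s)
      for (int m = 0; m < N; ++m) attempt(T, false);
    if (cost < best_running) best_running = cost;
    trace.push_back(best_running);
  }

  // zero-temperature polish
  for (int iter = 0; iter < max_polish_mcs; ++iter) {
    bool improved = false;
    for (int m = 0; m < N; ++m)
      if (attempt(0.0, true) < 0.0) improved = true;
    if (!improved) break;
  }

  cost = cpp_cost(A, dpow);  // re-derive exactly, no accumulation drift
  return List::create(_["perm"] = IntegerVector(perm.begin(), perm.end()),
                      _["cost"] = cost,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Exhaustive minimisation over all N! orders, enumerated lexicographically;
// the first strict minimiser wins, so ties break to the lexicographically
// smallest permutation. Caller guards N.
// [[Rcpp::export]]
List cpp_exhaustive(const IntegerMatrix &A, const NumericVector &dpow) {
  const int N = A.nrow();
  std::vector<int> p(N);
  for (int i = 0; i < N; ++i) p[i] = i;
  IntegerVector pv(p.begin(), p.end());
  double best = cpp_cost_perm(A, pv, dpow);
  std::vector<int> bestp = p;
  while (std::next_permutation(p.begin(), p.end())) {
    std::copy(p.begin(), p.end(), pv.begin());
    const double F = cpp_cost_perm(A, pv, dpow);
    if (F < best - 1e-12) {
      best = F;
      bestp = p;
    }
  }
  return List::create(_["perm"] = IntegerVector(bestp.begin(), bestp.end()),
                      _["cost"] = best);
}
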