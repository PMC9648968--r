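#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stationary distribution of the FSP-truncated telegraph generator.
//
// States are interleaved s = 2n + g (g = 0 OFF, 1 ON, n = 0..K), giving a
// banded transpose-generator with two sub/super-diagonals. The singular
// balance system is solved by fixing the last state's probability to one,
// dropping its (redundant) balance equation, and solving the remaining
// banded system with LAPACK's partial-pivoting band solver; the result is
// normalized to a probability vector. Callers guard the reducible cases
// (sigma_on = 0, sigma_off = 0, rho = 0) with their analytic limits.
// [[Rcpp::export]]
NumericVector cpp_telegraph_stationary(double s_on, double s_off, double rho,
                                       double d, int K) {
  // fix the ON state nearest the distribution mean (a high-probability
  // state keeps the bordered solve well-scaled even for steeply decaying
  // tails), drop its redundant balance equation, solve the remaining
  // banded system, then renormalize
  double mn = rho * (s_on / (s_on + s_off)) / d;
  int n_fix = (int) std::lround(mn);
  if (n_fix < 0) n_fix = 0;
  if (n_fix > K) n_fix = K;
  const int s_fix = 2 * n_fix + 1;           // interleaved index of (1, n_fix)
  const int n_all = 2 * (K + 1);
  const int n = n_all - 1;                   // unknowns after removing s_fix
  const int kl = 3, ku = 3, ldab = 2 * kl + ku + 1;
  std::vector<double> ab((size_t) ldab * n, 0.0);
  std::vector<double> b(n, 0.0);
  std::vector<int> ipiv(n);

  auto red = [&](int s) { return s < s_fix ? s : s - 1; };  // compacted index
  // B(i, j) = rate(j -> i) for i != j, B(j, j) = -out(j); equation for
  // s_fix dropped, column s_fix moved to the right-hand side (v_fix = 1)
  auto set = [&](int i, int j, double v) {
    if (i == s_fix) return;                  // dropped equation
    if (j == s_fix) { b[red(i)] -= v; return; }
    int ii = red(i), jj = red(j);
    ab[(size_t) ldab * jj + (kl + ku + ii - jj)] += v;
  };

  for (int m = 0; m <= K; ++m) {
    int off = 2 * m, on = 2 * m + 1;
    set(off, off, -(s_on + m * d));
    set(on, on, -(s_off + m * d + (m < K ? rho : 0.0)));
    set(on, off, s_on);
    set(off, on, s_off);
    if (m >= 1) {
      set(off - 2, off, m * d);
      set(on - 2, on, m * d);
    }
    if (m < K) set(on + 2, on, rho);
  }

  int info = 0, nrhs = 1, N = n, KL = kl, KU = ku, LDAB = ldab;
  F77_CALL(dgbsv)(&N, &KL, &KU, &nrhs, ab.data(), &LDAB, ipiv.data(),
                  b.data(), &N, &info);
  if (info != 0) stop("banded solve failed (LAPACK dgbsv info = %d)", info);

  NumericVector p(K + 1);
  double tot = 0.0;
  for (int m = 0; m <= K; ++m) {
    int off = 2 * m, on = 2 * m + 1;
    double v0 = (off == s_fix) ? 1.0 : b[red(off)];
    double v1 = (on == s_fix) ? 1.0 : b[red(on)];
    double pm = v0 + v1;
    if (pm < 0) pm = 0;
    p[m] = pm;
    tot += pm;
  }
  if (tot <= 0) stop("banded solve returned a non-positive distribution");
  for (int m = 0; m <= K; ++m) p[m] /= tot;
  return p;
}

// Transient counting process of the delay telegraph model over window tau
// by uniformization: P(k) = number of initiations while promoter-gated,
// started from stationary promoter occupancy. Returns the k-marginal.
// [[Rcpp::export]]
NumericVector cpp_delay_counting(double s_on, double s_off, double rho,
                                 double tau, int K, double eps) {
  double f_on = s_on / (s_on + s_off);
  std::vector<double> p_off(K + 1, 0.0), p_on(K + 1, 0.0);
  std::vector<double> q_off(K + 1), q_on(K + 1);
  std::vector<double> acc(2 * (K + 1), 0.0);
  p_off[0] = 1.0 - f_on;
  p_on[0] = f_on;

  double lam = s_on + s_off + rho;
  double a = lam * tau;
  int m_max = (int) std::ceil(a + 12.0 * std::sqrt(a + 1.0) + 30.0);

  double w = R::dpois(0.0, a, 0);  // Poisson time-mixture weight at m = 0
  for (int k = 0; k <= K; ++k) {
    acc[k] += w * p_off[k];
    acc[K + 1 + k] += w * p_on[k];
  }
  for (int m = 1; m <= m_max; ++m) {
    // one substochastic step of I + Q / lam
    for (int k = 0; k <= K; ++k) {
      q_off[k] = p_off[k] + (-s_on * p_off[k] + s_off * p_on[k]) / lam;
      double inflow = (k >= 1) ? (rho / lam) * p_on[k - 1] : 0.0;
      q_on[k] = p_on[k] + (s_on * p_off[k] - (s_off + rho) * p_on[k]) / lam
        + inflow;
    }
    p_off.swap(q_off);
    p_on.swap(q_on);
    w = R::dpois((double) m, a, 0);
    for (int k = 0; k <= K; ++k) {
      acc[k] += w * p_off[k];
      acc[K + 1 + k] += w * p_on[k];
    }
    if (w < eps * 1e-4 && m > a) break;
  }
  NumericVector out(K + 1);
  for (int k = 0; k <= K; ++k) out[k] = acc[k] + acc[K + 1 + k];
  return out;
}
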