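// Master-equation propagation for the island-assembly likelihood.
//
// Between observed events (colonisation, branching points, the present) the
// hidden-state probability vectors obey a linear system dQ/dt = A Q whose
// generator A is constant in time (rates depend on the hidden species count n
// and the number of phylogeny lineages k, not on t).  Each segment is
// therefore propagated exactly with a matrix exponential, which is robust to
// the extreme stiffness that arises under fast-turnover parameter regimes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Diversity-dependent per-species rate: linear decline towards the carrying
// capacity K, clamped at zero; K = Inf disables the feedback.
static inline double ddr(double base, double n, double K) {
  if (!std::isfinite(K)) return base;
  double r = base * (1.0 - n / K);
  return r > 0.0 ? r : 0.0;
}

// Generator for the two-channel system used while k = 0 or k >= 2.
// State layout: [ Q_n^k (n = 0..nmax) ; Q_n^{M,k} (n = 0..nmax) ].
static arma::mat generator_two(int k, int nmax, double gam, double lac,
                               double laa, double mu, double K) {
  const int lx = nmax + 1;
  arma::mat A(2 * lx, 2 * lx, arma::fill::zeros);
  for (int n = 0; n <= nmax; ++n) {
    const int i = n;        // Q_n^k
    const int j = lx + n;   // Q_n^{M,k}
    // gains into Q_n^k
    A(i, j) += mu;                                     // mainland pop extinction
    if (n >= 1) A(i, lx + n - 1) += laa;               // anagenesis of immigrant
    if (n >= 2) A(i, lx + n - 2) += ddr(lac, n + k - 1, K); // immigrant cladogenesis
    if (n >= 1) A(i, n - 1) += ddr(lac, n + k - 1, K) * (n + 2.0 * k - 1.0);
    if (n + 1 <= nmax) A(i, n + 1) += mu * (n + 1.0);
    // losses from Q_n^k
    A(i, i) -= (mu + ddr(lac, n + k, K)) * (n + k);
    A(i, i) -= ddr(gam, n + k, K);
    // gains into Q_n^{M,k}
    A(j, i) += ddr(gam, n + k, K);
    if (n >= 1) A(j, lx + n - 1) += ddr(lac, n + k, K) * (n + 2.0 * k - 1.0);
    if (n + 1 <= nmax) A(j, lx + n + 1) += mu * (n + 1.0);
    // losses from Q_n^{M,k}
    A(j, j) -= (mu + ddr(lac, n + k + 1, K)) * (n + k);
    A(j, j) -= (mu + laa + ddr(lac, n + k + 1, K));
  }
  return A;
}

// Generator for the three-channel system used while k = 1 (between the
// colonisation and the first branching point, if any).
// State layout: [ Q_n^1 ; Q_n^{M,1} ; Q_{M,n} ] with n = 0..nmax each.
static arma::mat generator_k1(int nmax, double gam, double lac, double laa,
                              double mu, double K) {
  const int lx = nmax + 1;
  arma::mat A(3 * lx, 3 * lx, arma::fill::zeros);
  for (int n = 0; n <= nmax; ++n) {
    const int i = n;            // Q_n^1
    const int j = lx + n;       // Q_n^{M,1}
    const int m = 2 * lx + n;   // Q_{M,n}
    // gains into Q_n^1
    A(i, m) += laa;                                    // anagenesis of surviving immigrant
    if (n >= 1) A(i, 2 * lx + n - 1) += 2.0 * ddr(lac, n, K);
    A(i, j) += mu;
    if (n >= 1) A(i, lx + n - 1) += laa;
    if (n >= 2) A(i, lx + n - 2) += ddr(lac, n, K);
    if (n >= 1) A(i, n - 1) += ddr(lac, n, K) * (n + 1.0);
    if (n + 1 <= nmax) A(i, n + 1) += mu * (n + 1.0);
    // losses from Q_n^1
    A(i, i) -= (mu + ddr(lac, n + 1, K)) * (n + 1.0);
    A(i, i) -= ddr(gam, n + 1, K);
    // gains into Q_n^{M,1}
    A(j, i) += ddr(gam, n + 1, K);
    if (n >= 1) A(j, lx + n - 1) += ddr(lac, n + 1, K) * (n + 1.0);
    if (n + 1 <= nmax) A(j, lx + n + 1) += mu * (n + 1.0);
    // losses from Q_n^{M,1}
    A(j, j) -= (mu + ddr(lac, n + 2, K)) * (n + 1.0);
    A(j, j) -= (mu + laa + ddr(lac, n + 2, K));
    // gains into Q_{M,n}
    if (n + 1 <= nmax) A(m, 2 * lx + n + 1) += mu * (n + 1.0);
    if (n >= 1) A(m, 2 * lx + n - 1) += ddr(lac, n, K) * (n - 1.0);
    // losses from Q_{M,n}: extinction/cladogenesis of all n+1 island species,
    // anagenesis of the surviving immigrant (moves to Q_n^1), and
    // re-immigration, which would reset the observed divergence time.
    A(m, m) -= (mu + ddr(lac, n + 1, K)) * (n + 1.0);
    A(m, m) -= laa + ddr(gam, n + 1, K);
  }
  return A;
}

// [[Rcpp::export(name = ".cpp_propagate")]]
arma::vec cpp_propagate(const arma::vec& q, double dt, int k, int nmax,
                        double gam, double lac, double laa, double mu,
                        double K) {
  arma::mat A = (k == 1) ? generator_k1(nmax, gam, lac, laa, mu, K)
                         : generator_two(k, nmax, gam, lac, laa, mu, K);
  if ((int)q.n_elem != (int)A.n_rows)
    stop("state vector length does not match generator dimension");
  arma::mat E = arma::expmat(A * dt);
  return E * q;
}

// [[Rcpp::export(name = ".cpp_dd_rate")]]
double cpp_dd_rate(double base, double n, double K) {
  return ddr(base, n, K);
}
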