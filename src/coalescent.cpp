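#include <Rcpp.h>
using namespace Rcpp;

// Batch Kingman-coalescent simulation with exponential growth, returning the
// site frequency spectrum of each replicate (infinite-sites mutation).
//
// Conventions follow the classical ms simulator: time in units of 4N0
// generations, theta0 = 4*N0*mu per locus, population size N(t) = N0 *
// exp(-alpha t) backward in time, so the pair coalescence rate at backward
// time t is exp(alpha t). Mutations fall as a Poisson process of rate
// theta0/2 per unit branch length; a mutation on a lineage subtending c
// leaves adds one site with derived-allele count c (1 <= c <= n-1).
//
// theta0 / alpha are per-replicate vectors of equal length; the return is an
// (n-1) x B integer matrix of SFS counts xi_1..xi_{n-1}.
// [[Rcpp::export]]
IntegerMatrix sfs_batch_cpp(int n, NumericVector theta0, NumericVector alpha) {
  if (n < 2) stop("n must be >= 2");
  R_xlen_t B = theta0.size();
  if (alpha.size() != B) stop("theta0 and alpha must have equal length");
  IntegerMatrix xi(n - 1, B);
  std::vector<int> cnt(n);

  for (R_xlen_t b = 0; b < B; ++b) {
    double th = theta0[b], a = alpha[b];
    if (th < 0) stop("theta0 must be nonnegative");
    for (int i = 0; i < n; ++i) cnt[i] = 1;
    double t = 0.0;
    int k = n;
    while (k >= 2) {
      double rate = k * (k - 1) / 2.0;
      double E = R::exp_rand();
      double dt;
      if (a == 0.0) {
        dt = E / rate;
      } else {
        // solve rate * (exp(a(t+dt)) - exp(at)) / a = E for dt
        dt = std::log(std::exp(a * t) + a * E / rate) / a - t;
      }
      if (th > 0) {
        double mu_mean = th * dt / 2.0;
        for (int i = 0; i < k; ++i) {
          int m = (int) R::rpois(mu_mean);
          if (m > 0) xi(cnt[i] - 1, b) += m;
        }
      }
      // merge a uniformly chosen pair
      int i = (int) (unif_rand() * k);
      if (i == k) i = k - 1;
      int j = (int) (unif_rand() * (k - 1));
      if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      cnt[i] += cnt[j];
      cnt[j] = cnt[k - 1];
      t += dt;
      --k;
    }
  }
  return xi;
}
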