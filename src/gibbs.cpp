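#include <Rcpp.h>
using namespace Rcpp;

// Data-augmented Gibbs chain for the normalized mixture likelihood.
//
// Unambiguous rows contribute fixed counts (base_counts). Ambiguous rows
// are collapsed equivalence groups: group g covers entries
// grp_ptr[g]..grp_ptr[g+1]-1 of grp_cols (0-based transcript index) and
// grp_p (conditional read probabilities), with multiplicity grp_w[g].
// Each sweep draws multinomial assignment counts per group (sequential
// binomial splitting) given x, then x ~ Dirichlet(1 + counts).
// Uses R's RNG, so seeding with set.seed() from R makes chains
// reproducible.
//
// [[Rcpp::export]]
NumericMatrix gibbs_chain_cpp(int n, int iterations, int burn_in, int thin,
                              IntegerVector base_counts,
                              IntegerVector grp_ptr, IntegerVector grp_cols,
                              NumericVector grp_p, IntegerVector grp_w) {
  int keep = iterations / thin;
  int ngrp = grp_w.size();
  NumericMatrix out(keep, n);
  std::vector<double> x(n), q(64);
  std::vector<int> counts(n);

  // initialize from a uniform Dirichlet draw
  double tot = 0.0;
  for (int j = 0; j < n; ++j) {
    x[j] = R::rgamma(1.0, 1.0);
    tot += x[j];
  }
  for (int j = 0; j < n; ++j) x[j] /= tot;

  int total_iter = burn_in + iterations;
  int saved = 0;
  for (int it = 0; it < total_iter; ++it) {
    for (int j = 0; j < n; ++j) counts[j] = base_counts[j];
    for (int g = 0; g < ngrp; ++g) {
      int s = grp_ptr[g], e = grp_ptr[g + 1];
      int k = e - s;
      if ((int)q.size() < k) q.resize(k);
      double qs = 0.0;
      for (int t = 0; t < k; ++t) {
        q[t] = x[grp_cols[s + t]] * grp_p[s + t];
        qs += q[t];
      }
      int remaining = grp_w[g];
      double denom = qs;
      for (int t = 0; t < k - 1 && remaining > 0; ++t) {
        double pr = q[t] / denom;
        if (pr > 1.0) pr = 1.0;
        int c = (int)R::rbinom((double)remaining, pr);
        counts[grp_cols[s + t]] += c;
        remaining -= c;
        denom -= q[t];
        if (denom <= 0.0) denom = 1e-300;
      }
      if (remaining > 0) counts[grp_cols[e - 1]] += remaining;
    }
    tot = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] = R::rgamma(1.0 + counts[j], 1.0);
      tot += x[j];
    }
    for (int j = 0; j < n; ++j) x[j] /= tot;
    int post = it - burn_in + 1;
    if (post > 0 && post % thin == 0) {
      for (int j = 0; j < n; ++j) out(saved, j) = x[j];
      ++saved;
    }
  }
  return out;
}
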