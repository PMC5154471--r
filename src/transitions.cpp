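// Hot loop of the acceptance-rejection transition sweep: one uniform per
// particle, exact exponential one-step probability, destination partition
// proportional to rates.  Uses R's RNG stream, so results are identical
// in distribution and reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector transition_sweep(IntegerVector state, IntegerVector rule_from,
                               IntegerVector rule_to, NumericMatrix rates,
                               double dt, double guard) {
  const int n = state.size();
  const int m = rule_from.size();
  if (rates.nrow() != n || rates.ncol() != m)
    stop("rates must be n_particles x n_rules");
  IntegerVector out(clone(state));
  RNGScope scope;
  std::vector<double> k(m);
  for (int i = 0; i < n; ++i) {
    const int s = state[i];
    double ktot = 0.0;
    for (int j = 0; j < m; ++j) {
      double r = 0.0;
      if (rule_from[j] == s) {
        r = rates(i, j);
        if (ISNAN(r) || r < 0) stop("negative transition rate");
        if (r * dt >= guard)
          stop("rate * dt = %g >= %g for rule %d: decrease dt "
               "(at most one transition per particle per step)",
               r * dt, guard, j + 1);
        ktot += r;
      }
      k[j] = r;
    }
    const double u = unif_rand();   // one draw per particle, always
    if (ktot <= 0.0) continue;
    const double p = -expm1(-ktot * dt);
    if (u >= p) continue;
    double thresh = 0.0;
    const double scale = p / ktot;
    for (int j = 0; j < m; ++j) {
      thresh += k[j] * scale;
      if (u < thresh) { out[i] = rule_to[j]; break; }
    }
  }
  return out;
}
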