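// Per-particle accumulation kernels for the hybrid engine.  Particle
// populations are sparse relative to (cells x realizations), so sources
// are accumulated by one pass over the particles instead of dense
// algebra on binned count matrices.
#include <Rcpp.h>
using namespace Rcpp;

// src[cell, real] += coef * [w_cell[cell]] * [w_real[real]] * [F(cell, real)]
// over particles whose state equals `si`; optional factors are skipped
// when the corresponding argument has length 0 (w_*) or use_F is false.
// [[Rcpp::export]]
NumericMatrix accumulate_particles(int ncell, int nreal, IntegerVector cell,
                                   IntegerVector real, IntegerVector state,
                                   int si, double coef,
                                   NumericVector w_cell, NumericVector w_real,
                                   NumericMatrix F, bool use_F) {
  NumericMatrix src(ncell, nreal);
  const int np = cell.size();
  const bool wc = w_cell.size() > 0, wr = w_real.size() > 0;
  for (int i = 0; i < np; ++i) {
    if (state[i] != si) continue;
    const int c = cell[i] - 1, r = real[i] - 1;
    double v = coef;
    if (wc) v *= w_cell[c];
    if (wr) v *= w_real[r];
    if (use_F) v *= F(c, r);
    src(c, r) += v;
  }
  return src;
}

// like accumulate_particles but adds into an existing matrix in place
// (the matrix must be freshly allocated by the engine, never user data)
// [[Rcpp::export]]
void accumulate_particles_into(NumericMatrix src, IntegerVector cell,
                               IntegerVector real, IntegerVector state,
                               int si, double coef, NumericVector w_cell,
                               NumericVector w_real, NumericMatrix F,
                               bool use_F) {
  const int np = cell.size();
  const bool wc = w_cell.size() > 0, wr = w_real.size() > 0;
  for (int i = 0; i < np; ++i) {
    if (state[i] != si) continue;
    const int c = cell[i] - 1, r = real[i] - 1;
    double v = coef;
    if (wc) v *= w_cell[c];
    if (wr) v *= w_real[r];
    if (use_F) v *= F(c, r);
    src(c, r) += v;
  }
}

// per-particle linear rate coef * max(F[cell, real], 0) + offset;
// counts clamped negative field values
// [[Rcpp::export]]
List gather_linear_rate(NumericMatrix F, IntegerVector cell,
                        IntegerVector real, double coef, double offset) {
  const int np = cell.size();
  NumericVector out(np);
  int neg = 0;
  for (int i = 0; i < np; ++i) {
    double v = F(cell[i] - 1, real[i] - 1);
    if (v < 0) { ++neg; v = 0.0; }
    out[i] = coef * v + offset;
  }
  return List::create(_["rate"] = out, _["n_negative"] = neg);
}

// src += rate * (target - F), in place (src freshly allocated by the engine)
// [[Rcpp::export]]
void add_relax_into(NumericMatrix src, NumericMatrix F, double rate,
                    double target) {
  const R_xlen_t n = src.size();
  if (F.size() != n) stop("shape mismatch");
  for (R_xlen_t i = 0; i < n; ++i) src[i] += rate * (target - F[i]);
}
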