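// Gibson-Bruck next-reaction stochastic simulation of well-mixed
// reaction networks with mass-action propensities (order 0, 1 or 2).
// Used as a statistically exact, time-discretization-free reference for
// the hybrid solver in its well-mixed (fast diffusion) limit.
#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

namespace {

// indexed binary min-heap over reaction firing times
struct IndexedHeap {
  std::vector<int> heap;      // heap of reaction ids
  std::vector<int> pos;       // position of reaction id in heap
  std::vector<double> key;    // firing times

  void init(int m) {
    heap.resize(m); pos.resize(m); key.assign(m, 0.0);
    for (int i = 0; i < m; ++i) { heap[i] = i; pos[i] = i; }
  }
  void swap_nodes(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (key[heap[i]] < key[heap[p]]) { swap_nodes(i, p); i = p; }
      else break;
    }
  }
  void down(int i) {
    int n = heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, s = i;
      if (l < n && key[heap[l]] < key[heap[s]]) s = l;
      if (r < n && key[heap[r]] < key[heap[s]]) s = r;
      if (s == i) break;
      swap_nodes(i, s); i = s;
    }
  }
  void heapify() {
    for (int i = (int)heap.size() / 2 - 1; i >= 0; --i) down(i);
  }
  void update(int id, double t) {
    double old = key[id]; key[id] = t;
    if (t < old) up(pos[id]); else down(pos[id]);
  }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

inline double propensity(const std::vector<double>& x, double k,
                         int r1, int r2) {
  if (r1 < 0) return k;                      // zeroth order
  if (r2 < 0) return k * x[r1];              // first order
  if (r1 == r2) return k * x[r1] * (x[r1] - 1.0) / 2.0;
  return k * x[r1] * x[r2];
}

} // namespace

//' @name gb_simulate
//' @title Low-level Gibson-Bruck simulator (C++ core)
//' @description Simulates `nreal` independent realizations of a
//'   well-mixed mass-action network by the next-reaction method and
//'   samples the piecewise-constant trajectories at `times`.
//'   R-facing wrapper: [gibson_bruck_simulate()].
//' @param x0 integer vector of initial copy numbers.
//' @param kvec per-reaction rate constants.
//' @param react1,react2 0-based reactant indices (-1 for none); a
//'   reaction is at most bimolecular.
//' @param stoich nreact x nspecies integer matrix of copy-number changes.
//' @param times strictly increasing output times.
//' @param nreal number of realizations.
//' @param max_events per-realization event cap (error when exceeded).
//' @return numeric array dim c(length(times), nspecies, nreal).
//' @keywords internal
// [[Rcpp::export]]
NumericVector gb_simulate(IntegerVector x0, NumericVector kvec,
                          IntegerVector react1, IntegerVector react2,
                          IntegerMatrix stoich, NumericVector times,
                          int nreal, double max_events = 5e8) {
  const int ns = x0.size();
  const int m = kvec.size();
  const int nt = times.size();
  if (stoich.nrow() != m || stoich.ncol() != ns)
    stop("stoich must be nreact x nspecies");
  const double t_end = times[nt - 1];

  // dependency graph: reaction i affects reaction j if i changes one of
  // j's reactants; i always affects itself (its own tau is redrawn).
  std::vector< std::vector<int> > dep(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      bool affects = (i == j);
      if (!affects) {
        if (react1[j] >= 0 && stoich(i, react1[j]) != 0) affects = true;
        if (react2[j] >= 0 && stoich(i, react2[j]) != 0) affects = true;
      }
      if (affects) dep[i].push_back(j);
    }
  }

  NumericVector out(Dimension(nt, ns, nreal));
  const double inf = std::numeric_limits<double>::infinity();
  RNGScope scope;
  double events_total = 0.0;

  for (int r = 0; r < nreal; ++r) {
    std::vector<double> x(ns);
    for (int s = 0; s < ns; ++s) x[s] = x0[s];
    std::vector<double> a(m);
    IndexedHeap h; h.init(m);
    for (int j = 0; j < m; ++j) {
      a[j] = propensity(x, kvec[j], react1[j], react2[j]);
      if (a[j] < 0) stop("negative propensity");
      h.key[j] = (a[j] > 0) ? exp_rand() / a[j] : inf;
    }
    h.heapify();
    double t = 0.0;
    int it = 0;
    while (it < nt) {
      int jmin = h.top();
      double tnext = h.top_key();
      // flush outputs up to the next event (or the end)
      while (it < nt && times[it] < tnext) {
        for (int s = 0; s < ns; ++s) out[it + nt * (s + ns * r)] = x[s];
        ++it;
      }
      if (it >= nt || tnext > t_end || !R_FINITE(tnext)) {
        // zero-propensity deadlock or horizon reached: state is frozen,
        // remaining outputs already flushed (completed early)
        while (it < nt) {
          for (int s = 0; s < ns; ++s) out[it + nt * (s + ns * r)] = x[s];
          ++it;
        }
        break;
      }
      // fire reaction jmin at tnext
      t = tnext;
      for (int s = 0; s < ns; ++s) x[s] += stoich(jmin, s);
      if (++events_total > max_events)
        stop("event cap exceeded (%.3g events); reduce the problem size",
             max_events);
      for (size_t q = 0; q < dep[jmin].size(); ++q) {
        int j = dep[jmin][q];
        double anew = propensity(x, kvec[j], react1[j], react2[j]);
        if (anew < 0) stop("negative propensity");
        double tj;
        if (j == jmin) {
          tj = (anew > 0) ? t + exp_rand() / anew : inf;
        } else {
          double aold = a[j];
          double told = h.key[j];
          if (anew <= 0) tj = inf;
          else if (aold <= 0 || !R_FINITE(told))
            tj = t + exp_rand() / anew;   // absolute-time reuse impossible
          else
            tj = t + (aold / anew) * (told - t);
        }
        a[j] = anew;
        h.update(j, tj);
      }
    }
  }
  return out;
}
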