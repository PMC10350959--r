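#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method stochastic simulation over the shared channel table.
//
// Channels are unordered pairs (i, j), i <= j, i + j <= N. The propensity
// vector is laid out as [aggregation channels, fragmentation channels] and
// per event two uniform variates are drawn in the order (u1 waiting time,
// u2 channel selection), matching the R reference engine draw for draw.
//
// The state is sampled onto `grid` by left-continuous piecewise-constant
// interpolation: the state holds until the next event. Grid times beyond
// t_max receive the state frozen at t_max.
// [[Rcpp::export]]
List ssa_run(IntegerVector ii, IntegerVector jj, IntegerVector kk,
             NumericVector Kv, NumericVector Fv,
             int N, double V, double t_max, NumericVector grid,
             IntegerVector n0, bool record_events, double max_events) {
  const int nch = ii.size();
  const int G = grid.size();
  std::vector<int> n(n0.begin(), n0.end());
  std::vector<double> a(2 * nch);
  IntegerMatrix counts(G, N);
  std::vector<double> ev_t;
  std::vector<int> ev_ch; // +c aggregation, -c fragmentation (1-based c)

  double t = 0.0;
  int g = 0;
  double n_events = 0.0;
  bool absorbed = false;

  while (true) {
    // propensities
    double a_tot = 0.0;
    for (int c = 0; c < nch; ++c) {
      int i = ii[c] - 1, j = jj[c] - 1, k = kk[c] - 1;
      double aa;
      if (i == j)
        aa = Kv[c] * n[i] * (n[i] - 1) / (2.0 * V);
      else
        aa = Kv[c] * n[i] * n[j] / V;
      double af = Fv[c] * n[k];
      a[c] = aa;
      a[nch + c] = af;
      a_tot += aa + af;
    }

    if (a_tot <= 0.0) { absorbed = true; break; }

    double u1 = unif_rand();
    double tau = std::log(1.0 / u1) / a_tot;
    double t_next = t + tau;

    if (t_next > t_max) {
      t = t_max;
      break;
    }

    // sample grid points passed before this event fires
    while (g < G && grid[g] < t_next) {
      for (int s = 0; s < N; ++s) counts(g, s) = n[s];
      ++g;
    }

    // select channel: smallest index with cumulative sum >= u2 * a_tot
    double u2 = unif_rand();
    double target = u2 * a_tot, cum = 0.0;
    int sel = 2 * nch - 1;
    for (int c = 0; c < 2 * nch; ++c) {
      cum += a[c];
      if (cum >= target) { sel = c; break; }
    }

    // execute
    int c = sel % nch;
    int i = ii[c] - 1, j = jj[c] - 1, k = kk[c] - 1;
    if (sel < nch) {        // aggregation: C_i + C_j -> C_{i+j}
      n[i] -= 1; n[j] -= 1; n[k] += 1;
    } else {                // fragmentation: C_{i+j} -> C_i + C_j
      n[i] += 1; n[j] += 1; n[k] -= 1;
    }
    t = t_next;
    n_events += 1.0;
    if (record_events) {
      ev_t.push_back(t);
      ev_ch.push_back(sel < nch ? (c + 1) : -(c + 1));
    }
    if (n_events >= max_events)
      stop("event cap reached (%.0f events before t = %g)", n_events, t);
  }

  // remaining grid points hold the final (frozen or t_max) state
  for (; g < G; ++g)
    for (int s = 0; s < N; ++s) counts(g, s) = n[s];

  return List::create(_["counts"] = counts,
                      _["final_state"] = IntegerVector(n.begin(), n.end()),
                      _["t_end"] = t,
                      _["n_events"] = n_events,
                      _["absorbed"] = absorbed,
                      _["event_times"] = NumericVector(ev_t.begin(), ev_t.end()),
                      _["event_channel"] = IntegerVector(ev_ch.begin(), ev_ch.end()));
}
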