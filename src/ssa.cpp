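#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Exact direct-method Gillespie SSA over a flattened (species x compartment)
// state vector. Channels are fully expanded by the R layer: a channel has a
// stochastic rate constant, up to two reactant state indices and up to four
// product state indices (reactants are consumed, products created; catalytic
// species appear on both sides). First-order transport between compartments
// is expressed as a channel whose product is the same species in another
// compartment, so reactions and exchange share one code path.
//
// [[Rcpp::export]]
List ssa_core(IntegerVector init,
              IntegerVector ch_order,
              IntegerVector ch_r1,
              IntegerVector ch_r2,
              List ch_products,
              NumericVector ch_rate,
              double duration,
              double record_interval,
              int seed,
              int stream) {
  const int n_state = init.size();
  const int n_ch = ch_rate.size();

  std::vector<double> x(n_state);
  for (int i = 0; i < n_state; ++i) x[i] = init[i];

  // products flattened
  std::vector<std::vector<int>> prods(n_ch);
  for (int c = 0; c < n_ch; ++c) {
    IntegerVector p = ch_products[c];
    prods[c].assign(p.begin(), p.end());
  }

  // dependency lists: state index -> channels whose propensity involves it
  std::vector<std::vector<int>> deps(n_state);
  for (int c = 0; c < n_ch; ++c) {
    if (ch_r1[c] >= 0) deps[ch_r1[c]].push_back(c);
    if (ch_r2[c] >= 0 && ch_r2[c] != ch_r1[c]) deps[ch_r2[c]].push_back(c);
  }

  std::vector<double> a(n_ch, 0.0);
  auto prop = [&](int c) -> double {
    switch (ch_order[c]) {
      case 0: return ch_rate[c];
      case 1: return ch_rate[c] * x[ch_r1[c]];
      default:
        if (ch_r1[c] == ch_r2[c]) {
          double n = x[ch_r1[c]];
          return ch_rate[c] * n * (n - 1.0) * 0.5;
        }
        return ch_rate[c] * x[ch_r1[c]] * x[ch_r2[c]];
    }
  };
  double a_tot = 0.0;
  for (int c = 0; c < n_ch; ++c) { a[c] = prop(c); a_tot += a[c]; }

  const int n_rec = (record_interval > 0)
                        ? (int)std::floor(duration / record_interval + 1e-9) + 1
                        : 2;
  const double rec_dt = (record_interval > 0) ? record_interval : duration;
  NumericMatrix rec(n_state, n_rec);
  NumericVector rec_times(n_rec);
  NumericVector tally(n_ch);
  NumericVector first_seen(n_state, -1.0);
  for (int i = 0; i < n_state; ++i)
    if (x[i] > 0) first_seen[i] = 0.0;

  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);

  double t = 0.0;
  int irec = 0;
  auto record_upto = [&](double tnow) {
    while (irec < n_rec && irec * rec_dt <= tnow + 1e-12) {
      for (int i = 0; i < n_state; ++i) rec(i, irec) = x[i];
      rec_times[irec] = irec * rec_dt;
      ++irec;
    }
  };

  // guard against propensity pathologies
  long long n_events = 0;
  while (t < duration) {
    if (a_tot <= 1e-300) { t = duration; break; }
    if (!std::isfinite(a_tot))
      stop("propensity overflow in SSA (a_tot is not finite)");
    double dt = rng.exp_rate(a_tot);
    if (t + dt > duration) { t = duration; break; }
    // select channel
    double u = rng.unif() * a_tot;
    int c = 0;
    double acc = 0.0;
    for (; c < n_ch - 1; ++c) {
      acc += a[c];
      if (u < acc) break;
    }
    record_upto(t + dt);
    t += dt;
    // execute
    if (ch_r1[c] >= 0) x[ch_r1[c]] -= 1.0;
    if (ch_r2[c] >= 0) x[ch_r2[c]] -= 1.0;
    for (int p : prods[c]) {
      x[p] += 1.0;
      if (first_seen[p] < 0 && x[p] > 0) first_seen[p] = t;
    }
    tally[c] += 1.0;
    ++n_events;
    // update propensities of affected channels
    auto touch = [&](int st) {
      for (int cc : deps[st]) {
        a_tot -= a[cc];
        a[cc] = prop(cc);
        a_tot += a[cc];
      }
    };
    if (ch_r1[c] >= 0) touch(ch_r1[c]);
    if (ch_r2[c] >= 0 && ch_r2[c] != ch_r1[c]) touch(ch_r2[c]);
    for (size_t k = 0; k < prods[c].size(); ++k) {
      int p = prods[c][k];
      bool dup = (p == ch_r1[c]) || (p == ch_r2[c]);
      for (size_t j = 0; j < k && !dup; ++j) dup = (prods[c][j] == p);
      if (!dup) touch(p);
    }
    // periodic full refresh to wash out float drift
    if ((n_events & 0xFFFF) == 0) {
      a_tot = 0.0;
      for (int cc = 0; cc < n_ch; ++cc) { a[cc] = prop(cc); a_tot += a[cc]; }
    }
  }
  record_upto(duration);

  IntegerVector final_state(n_state);
  for (int i = 0; i < n_state; ++i) final_state[i] = (int)x[i];

  return List::create(_["times"] = rec_times,
                      _["counts"] = rec,
                      _["tally"] = tally,
                      _["first_seen"] = first_seen,
                      _["final"] = final_state,
                      _["n_events"] = (double)n_events);
}
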