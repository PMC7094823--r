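#include <Rcpp.h>
#include <vector>
#include <cstring>
#include "rng.h"

using namespace Rcpp;

// Operator-split fixed-timestep RDME sampler.
//
// Per timestep tau:
//   1. diffusion: every molecule independently attempts one jump to a
//      uniformly chosen face neighbor with per-direction probability
//      D*tau/lambda^2 (<= 1/6). Jumps into sites whose type is not in the
//      species' allowed set are rejected (the molecule stays put, which
//      realizes reflecting obstacles and the box boundary). Crossings
//      nucleoplasm->speckle are accepted with an extra factor P_n and
//      speckle->nucleoplasm with P_s (the transition-probability bias that
//      realizes speckle partitioning).
//   2. reactions: within each subvolume containing at least one molecule of
//      a "trigger" species (any non-pool reactant), reaction events on
//      [t, t+tau] are sampled by an exact Gillespie sub-loop with
//      propensities recomputed after every event. Compartment restrictions
//      are enforced through the site type of the subvolume.
//
// Molecules are stored per species both as a position list (for diffusion)
// and as a dense per-site count array (for propensities), kept in sync.
// Abundant "pool" species skip the trigger scan but participate fully in
// diffusion and as reaction partners.

struct Engine {
  int nx, ny, nz;
  long N;
  const uint8_t* sites;
  int n_species;
  std::vector<double> p_dir;             // D*tau/lambda^2 per species
  std::vector<uint16_t> allowed;         // site-type bitmask per species
  std::vector<double> Pn, Ps;            // bias per species
  std::vector<char> is_trigger;
  int bias_from, bias_to;                // site-type codes (nucleoplasm, speckle)

  std::vector<std::vector<int>> pos;     // molecule site indices per species
  std::vector<std::vector<int32_t>> cnt; // dense per-site counts per species

  // reactions
  int n_re;
  std::vector<int> order, r1, r2;
  std::vector<std::vector<int>> prods;
  std::vector<double> rate;              // stochastic per-site rate
  std::vector<uint16_t> re_sitemask;

  std::vector<double> tally;
  std::vector<double> first_seen;

  void add_mol(int sp, int site, double t) {
    pos[sp].push_back(site);
    cnt[sp][site]++;
    if (first_seen[sp] < 0) first_seen[sp] = t;
  }
  void remove_mol(int sp, int site) {
    // O(n) scan; removals only happen on reaction events, which are rare
    // compared to diffusion moves
    std::vector<int>& v = pos[sp];
    for (size_t i = v.size(); i-- > 0;) {
      if (v[i] == site) {
        v[i] = v.back();
        v.pop_back();
        cnt[sp][site]--;
        return;
      }
    }
    Rcpp::stop("internal error: molecule bookkeeping out of sync");
  }

  inline double prop(int c, int site) const {
    if (order[c] == 1) return rate[c] * cnt[r1[c]][site];
    int a = cnt[r1[c]][site];
    if (a == 0) return 0.0;
    if (r1[c] == r2[c]) return rate[c] * a * (a - 1) * 0.5;
    int b = cnt[r2[c]][site];
    return b ? rate[c] * a * b : 0.0;
  }
};

// [[Rcpp::export]]
List rdme_core(RawVector sites, IntegerVector dims,
               double lambda, double tau, int n_steps, int record_every,
               List species_pos0,
               NumericVector D, IntegerVector allowed_mask,
               NumericVector Pn, NumericVector Ps, LogicalVector trigger,
               IntegerVector re_order, IntegerVector re_r1, IntegerVector re_r2,
               List re_products, NumericVector re_rate, IntegerVector re_sitemask,
               int bias_from, int bias_to,
               int seed, int stream,
               IntegerVector track_species) {
  Engine E;
  E.nx = dims[0]; E.ny = dims[1]; E.nz = dims[2];
  E.N = (long)E.nx * E.ny * E.nz;
  E.sites = (const uint8_t*)RAW(sites);
  E.n_species = D.size();
  E.bias_from = bias_from; E.bias_to = bias_to;

  const double inv_l2 = 1.0 / (lambda * lambda);
  E.p_dir.resize(E.n_species);
  for (int s = 0; s < E.n_species; ++s) {
    E.p_dir[s] = D[s] * tau * inv_l2;
    if (E.p_dir[s] > 1.0 / 6.0 + 1e-12)
      stop("tau too large: per-direction jump probability exceeds 1/6 for species %d", s + 1);
  }
  E.allowed.assign(allowed_mask.begin(), allowed_mask.end());
  E.Pn.assign(Pn.begin(), Pn.end());
  E.Ps.assign(Ps.begin(), Ps.end());
  E.is_trigger.assign(trigger.begin(), trigger.end());

  E.pos.resize(E.n_species);
  E.cnt.assign(E.n_species, std::vector<int32_t>(E.N, 0));
  E.first_seen.assign(E.n_species, -1.0);
  for (int s = 0; s < E.n_species; ++s) {
    IntegerVector p0 = species_pos0[s];
    E.pos[s].reserve(p0.size());
    for (int i = 0; i < p0.size(); ++i) E.add_mol(s, p0[i], 0.0);
    if (p0.size() == 0) E.first_seen[s] = -1.0;
  }

  E.n_re = re_rate.size();
  if (E.n_re > 64) stop("rdme_core supports at most 64 reaction channels");
  E.order.assign(re_order.begin(), re_order.end());
  E.r1.assign(re_r1.begin(), re_r1.end());
  E.r2.assign(re_r2.begin(), re_r2.end());
  E.rate.assign(re_rate.begin(), re_rate.end());
  E.re_sitemask.assign(re_sitemask.begin(), re_sitemask.end());
  E.prods.resize(E.n_re);
  for (int c = 0; c < E.n_re; ++c) {
    IntegerVector p = re_products[c];
    E.prods[c].assign(p.begin(), p.end());
  }
  E.tally.assign(E.n_re, 0.0);

  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);

  const int n_rec = n_steps / record_every + 1;
  const int n_types = 11;
  // recorded aggregate: species x site-type x time
  NumericVector rec(Dimension(E.n_species, n_types, n_rec));
  NumericVector rec_times(n_rec);
  List track_out(track_species.size() > 0 ? n_rec : 0);

  const long sxy = (long)E.nx * E.ny;
  int irec = 0;
  auto record = [&](int step) {
    rec_times[irec] = step * tau;
    for (int s = 0; s < E.n_species; ++s)
      for (int site : E.pos[s])
        rec[s + E.n_species * (E.sites[site] + n_types * irec)] += 1.0;
    if (track_species.size() > 0) {
      List snap(track_species.size());
      for (int k = 0; k < track_species.size(); ++k) {
        int s = track_species[k];
        snap[k] = IntegerVector(E.pos[s].begin(), E.pos[s].end());
      }
      track_out[irec] = snap;
    }
    ++irec;
  };
  record(0);

  std::vector<int> active;   // unique reactive sites this step
  std::vector<char> seen(E.N, 0);

  for (int step = 1; step <= n_steps; ++step) {
    // ---- diffusion ----
    for (int s = 0; s < E.n_species; ++s) {
      const double p = E.p_dir[s];
      if (p <= 0.0) continue;
      const double p6 = 6.0 * p;
      const uint16_t mask = E.allowed[s];
      const double pn = E.Pn[s], ps = E.Ps[s];
      std::vector<int>& v = E.pos[s];
      std::vector<int32_t>& c = E.cnt[s];
      const size_t nm = v.size();
      for (size_t m = 0; m < nm; ++m) {
        double u = rng.unif();
        if (u >= p6) continue;
        int dir = (int)(u / p);
        if (dir > 5) dir = 5;
        const int site = v[m];
        const int x = (int)(site % E.nx);
        const int yz = (int)(site / E.nx);
        const int y = yz % E.ny;
        const int z = yz / E.ny;
        long tgt;
        switch (dir) {
          case 0: if (x == E.nx - 1) continue; tgt = site + 1; break;
          case 1: if (x == 0) continue; tgt = site - 1; break;
          case 2: if (y == E.ny - 1) continue; tgt = site + E.nx; break;
          case 3: if (y == 0) continue; tgt = site - E.nx; break;
          case 4: if (z == E.nz - 1) continue; tgt = site + sxy; break;
          default: if (z == 0) continue; tgt = site - sxy; break;
        }
        const int tt = E.sites[tgt];
        if (!((mask >> tt) & 1)) continue;
        const int ft = E.sites[site];
        if (ft == bias_from && tt == bias_to) {
          if (pn < 1.0 && rng.unif() >= pn) continue;
        } else if (ft == bias_to && tt == bias_from) {
          if (ps < 1.0 && rng.unif() >= ps) continue;
        }
        c[site]--;
        c[tgt]++;
        v[m] = (int)tgt;
      }
    }

    // ---- reactions ----
    if (E.n_re > 0) {
      active.clear();
      for (int s = 0; s < E.n_species; ++s) {
        if (!E.is_trigger[s]) continue;
        for (int site : E.pos[s]) {
          if (!seen[site]) { seen[site] = 1; active.push_back(site); }
        }
      }
      const double t0 = (step - 1) * tau;
      for (int site : active) {
        seen[site] = 0;
        const int ty = E.sites[site];
        double t = 0.0;
        for (;;) {
          double a_tot = 0.0;
          double a[64];
          for (int c = 0; c < E.n_re; ++c) {
            double ac = ((E.re_sitemask[c] >> ty) & 1) ? E.prop(c, site) : 0.0;
            a[c] = ac;
            a_tot += ac;
          }
          if (a_tot <= 0.0) break;
          t += rng.exp_rate(a_tot);
          if (t > tau) break;
          double u = rng.unif() * a_tot;
          int c = 0;
          double acc = 0.0;
          for (; c < E.n_re - 1; ++c) { acc += a[c]; if (u < acc) break; }
          if (E.order[c] >= 1) E.remove_mol(E.r1[c], site);
          if (E.order[c] >= 2) E.remove_mol(E.r2[c], site);
          for (int pd : E.prods[c]) E.add_mol(pd, site, t0 + t);
          E.tally[c] += 1.0;
        }
      }
    }

    if (step % record_every == 0) record(step);
  }

  List final_pos(E.n_species);
  for (int s = 0; s < E.n_species; ++s)
    final_pos[s] = IntegerVector(E.pos[s].begin(), E.pos[s].end());

  return List::create(_["times"] = rec_times,
                      _["counts"] = rec,
                      _["tally"] = NumericVector(E.tally.begin(), E.tally.end()),
                      _["first_seen"] = NumericVector(E.first_seen.begin(), E.first_seen.end()),
                      _["final_pos"] = final_pos,
                      _["track"] = track_out);
}
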