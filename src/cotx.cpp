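#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Exact SSA for co-transcriptional splicing over coupled well-mixed
// compartments (0 = nucleoplasm, 1 = speckle).
//
// Transcripts are agents: a gene initiates a transcript whose first
// intron-exon unit is already exposed; the remaining units emerge
// sequentially at rate k_unit each (elongation). Every emerged, unspliced
// intron independently assembles a spliceosome through
// free -> E (+U1) -> A (+U2) -> B (+triU) -> B* (-U1) -> spliced (-U2,-triU),
// drawing on shared U1/U2/triU pools in the transcript's compartment.
// When all introns of a transcript are spliced the mature mRNA is released.
// Transcripts hop between compartments with first-order exchange rates
// (speckle bias); bound particles travel with their transcript. Pools hop
// with their own exchange rates.
//
// All propensities are population-level aggregates (counts of introns per
// stage per compartment), so the channel set stays small; the firing
// agent/intron is then drawn uniformly from the matching class.

enum Stage { UNEMERGED = 0, FREE = 1, CE = 2, CA = 3, CB = 4, CBS = 5, DONE = 6 };

struct Transcript {
  int comp;
  int emerged;
  int stage[8];  // up to 8 introns
};

// [[Rcpp::export]]
List cotx_core(int n_genes, int n_introns,
               double k_init, double k_unit,
               NumericVector pools0,   // U1, U2, triU initial counts (all in comp 0)
               NumericVector vols,     // compartment volumes in litres (len 2)
               NumericVector kon,      // kon1, kon2, kon3  (M^-1 s^-1)
               NumericVector koff,     // koff1, koff2, koff3 (s^-1)
               double k_act, double k_spl,
               NumericVector hop_in,   // per-molecule 0->1 rates: U1,U2,triU,transcript
               NumericVector hop_out,  // per-molecule 1->0 rates: U1,U2,triU,transcript
               double duration, double record_interval,
               int seed, int stream) {
  if (n_introns < 1 || n_introns > 8) stop("n_introns must be in 1..8");
  const double NA_ = 6.02214076e23;
  const int NC = 2;
  double c_on[3][2];
  for (int r = 0; r < 3; ++r)
    for (int cc = 0; cc < NC; ++cc)
      c_on[r][cc] = (vols[cc] > 0) ? kon[r] / (NA_ * vols[cc]) : 0.0;

  double pool[3][2] = {{pools0[0], 0}, {pools0[1], 0}, {pools0[2], 0}};
  double mRNA = 0.0;

  std::vector<Transcript> tr;
  tr.reserve(4096);

  // aggregate counters: introns per stage per compartment
  double nstage[7][2] = {{0}};
  double npend[2] = {0, 0};  // transcripts with emerged < n_introns
  double ntr[2] = {0, 0};

  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);

  const int n_rec = (record_interval > 0)
                        ? (int)std::floor(duration / record_interval + 1e-9) + 1
                        : 2;
  const double rec_dt = (record_interval > 0) ? record_interval : duration;
  // recorded rows: time, mRNA, free_transcripts, transcripts_n, transcripts_s,
  // U1_n, U1_s, U2_n, U2_s, triU_n, triU_s, bound_introns
  NumericMatrix rec(12, n_rec);
  int irec = 0;

  auto n_free_transcripts = [&]() {
    int nf = 0;
    for (const Transcript& T : tr) {
      bool bound = false;
      for (int i = 0; i < T.emerged && !bound; ++i)
        bound = (T.stage[i] >= CE && T.stage[i] <= CBS);
      if (!bound) ++nf;
    }
    return nf;
  };
  auto record_upto = [&](double tnow) {
    while (irec < n_rec && irec * rec_dt <= tnow + 1e-12) {
      double nb = 0;
      for (int st = CE; st <= CBS; ++st) nb += nstage[st][0] + nstage[st][1];
      rec(0, irec) = irec * rec_dt;
      rec(1, irec) = mRNA;
      rec(2, irec) = n_free_transcripts();
      rec(3, irec) = ntr[0];
      rec(4, irec) = ntr[1];
      rec(5, irec) = pool[0][0];  rec(6, irec) = pool[0][1];
      rec(7, irec) = pool[1][0];  rec(8, irec) = pool[1][1];
      rec(9, irec) = pool[2][0];  rec(10, irec) = pool[2][1];
      rec(11, irec) = nb;
      ++irec;
    }
  };

  // channel layout (per compartment where applicable):
  //  0: initiation (global)
  //  1,2: emergence per comp
  //  3..8:  bind U1 / bind U2 / bind triU  x comp
  //  9..14: koff1 / koff2 / koff3 x comp
  // 15,16: activation (B -> B*) x comp
  // 17,18: splice x comp
  // 19..24: pool hops (U1,U2,triU) x direction
  // 25,26: transcript hop 0->1, 1->0
  const int NCH = 27;
  double a[NCH];

  auto pick_intron = [&](int comp, int stage, Transcript*& Tout, int& iout) {
    double n = nstage[stage][comp];
    int k = (int)(rng.unif() * n);
    if (k >= (int)n) k = (int)n - 1;
    for (Transcript& T : tr) {
      if (T.comp != comp) continue;
      for (int i = 0; i < T.emerged; ++i) {
        if (T.stage[i] == stage) {
          if (k == 0) { Tout = &T; iout = i; return; }
          --k;
        }
      }
    }
    stop("internal error: intron counters out of sync");
  };

  double t = 0.0;
  while (t < duration) {
    for (int cc = 0; cc < NC; ++cc) {
      a[1 + cc] = k_unit * npend[cc];
      a[3 + cc] = c_on[0][cc] * pool[0][cc] * nstage[FREE][cc];
      a[5 + cc] = c_on[1][cc] * pool[1][cc] * nstage[CE][cc];
      a[7 + cc] = c_on[2][cc] * pool[2][cc] * nstage[CA][cc];
      a[9 + cc] = koff[0] * nstage[CE][cc];
      a[11 + cc] = koff[1] * nstage[CA][cc];
      a[13 + cc] = koff[2] * nstage[CB][cc];
      a[15 + cc] = k_act * nstage[CB][cc];
      a[17 + cc] = k_spl * nstage[CBS][cc];
    }
    a[0] = k_init * n_genes;
    for (int sp = 0; sp < 3; ++sp) {
      a[19 + 2 * sp] = hop_in[sp] * pool[sp][0];
      a[20 + 2 * sp] = hop_out[sp] * pool[sp][1];
    }
    a[25] = hop_in[3] * ntr[0];
    a[26] = hop_out[3] * ntr[1];

    double a_tot = 0.0;
    for (int c = 0; c < NCH; ++c) a_tot += a[c];
    if (a_tot <= 1e-300) { t = duration; break; }
    double dt = rng.exp_rate(a_tot);
    if (t + dt > duration) { t = duration; break; }
    record_upto(t + dt);
    t += dt;

    double u = rng.unif() * a_tot;
    int ch = 0;
    double acc = 0.0;
    for (; ch < NCH - 1; ++ch) { acc += a[ch]; if (u < acc) break; }

    if (ch == 0) {  // initiation: new transcript in nucleoplasm, unit 1 exposed
      Transcript T;
      T.comp = 0;
      T.emerged = 1;
      for (int i = 0; i < 8; ++i) T.stage[i] = UNEMERGED;
      T.stage[0] = FREE;
      tr.push_back(T);
      ntr[0] += 1;
      nstage[FREE][0] += 1;
      if (n_introns > 1) npend[0] += 1;
    } else if (ch == 1 || ch == 2) {  // next unit emerges
      int cc = ch - 1;
      double n = npend[cc];
      int k = (int)(rng.unif() * n);
      if (k >= (int)n) k = (int)n - 1;
      Transcript* T = nullptr;
      for (Transcript& X : tr) {
        if (X.comp == cc && X.emerged < n_introns) {
          if (k == 0) { T = &X; break; }
          --k;
        }
      }
      T->stage[T->emerged] = FREE;
      T->emerged += 1;
      nstage[FREE][cc] += 1;
      if (T->emerged == n_introns) npend[cc] -= 1;
    } else if (ch >= 3 && ch <= 18) {
      int cc = (ch - 3) % 2;
      int kind = (ch - 3) / 2;  // 0,1,2 bind; 3,4,5 unbind; 6 act; 7 splice
      Transcript* T;
      int i;
      switch (kind) {
        case 0:  // free + U1 -> E
          pick_intron(cc, FREE, T, i);
          T->stage[i] = CE; nstage[FREE][cc] -= 1; nstage[CE][cc] += 1;
          pool[0][cc] -= 1;
          break;
        case 1:  // E + U2 -> A
          pick_intron(cc, CE, T, i);
          T->stage[i] = CA; nstage[CE][cc] -= 1; nstage[CA][cc] += 1;
          pool[1][cc] -= 1;
          break;
        case 2:  // A + triU -> B
          pick_intron(cc, CA, T, i);
          T->stage[i] = CB; nstage[CA][cc] -= 1; nstage[CB][cc] += 1;
          pool[2][cc] -= 1;
          break;
        case 3:  // E -> free + U1
          pick_intron(cc, CE, T, i);
          T->stage[i] = FREE; nstage[CE][cc] -= 1; nstage[FREE][cc] += 1;
          pool[0][cc] += 1;
          break;
        case 4:  // A -> E + U2
          pick_intron(cc, CA, T, i);
          T->stage[i] = CE; nstage[CA][cc] -= 1; nstage[CE][cc] += 1;
          pool[1][cc] += 1;
          break;
        case 5:  // B -> A + triU
          pick_intron(cc, CB, T, i);
          T->stage[i] = CA; nstage[CB][cc] -= 1; nstage[CA][cc] += 1;
          pool[2][cc] += 1;
          break;
        case 6:  // B -> B* + U1
          pick_intron(cc, CB, T, i);
          T->stage[i] = CBS; nstage[CB][cc] -= 1; nstage[CBS][cc] += 1;
          pool[0][cc] += 1;
          break;
        default: {  // B* -> spliced + U2 + triU
          pick_intron(cc, CBS, T, i);
          T->stage[i] = DONE; nstage[CBS][cc] -= 1;
          pool[1][cc] += 1;
          pool[2][cc] += 1;
          bool done = (T->emerged == n_introns);
          for (int j = 0; j < n_introns && done; ++j) done = (T->stage[j] == DONE);
          if (done) {  // release mature mRNA, retire agent
            mRNA += 1;
            ntr[cc] -= 1;
            size_t idx = T - &tr[0];
            tr[idx] = tr.back();
            tr.pop_back();
          }
          break;
        }
      }
    } else if (ch >= 19 && ch <= 24) {  // pool hop
      int sp = (ch - 19) / 2;
      int dirin = ((ch - 19) % 2 == 0);
      if (dirin) { pool[sp][0] -= 1; pool[sp][1] += 1; }
      else { pool[sp][0] += 1; pool[sp][1] -= 1; }
    } else {  // transcript hop
      int from = (ch == 25) ? 0 : 1;
      int to = 1 - from;
      double n = ntr[from];
      int k = (int)(rng.unif() * n);
      if (k >= (int)n) k = (int)n - 1;
      Transcript* T = nullptr;
      for (Transcript& X : tr) {
        if (X.comp == from) {
          if (k == 0) { T = &X; break; }
          --k;
        }
      }
      // move agent and its stage tallies (bound particles travel along)
      for (int i = 0; i < T->emerged; ++i) {
        int st = T->stage[i];
        if (st >= FREE && st <= CBS) { nstage[st][from] -= 1; nstage[st][to] += 1; }
      }
      if (T->emerged < n_introns) { npend[from] -= 1; npend[to] += 1; }
      ntr[from] -= 1; ntr[to] += 1;
      T->comp = to;
    }
  }
  record_upto(duration);

  double nb = 0;
  for (int st = CE; st <= CBS; ++st) nb += nstage[st][0] + nstage[st][1];
  return List::create(
      _["record"] = rec,
      _["mRNA"] = mRNA,
      _["free_transcripts"] = (double)n_free_transcripts(),
      _["bound_introns"] = nb,
      _["transcripts"] = NumericVector::create(ntr[0], ntr[1]),
      _["U1"] = NumericVector::create(pool[0][0], pool[0][1]),
      _["U2"] = NumericVector::create(pool[1][0], pool[1][1]),
      _["triU"] = NumericVector::create(pool[2][0], pool[2][1]));
}
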