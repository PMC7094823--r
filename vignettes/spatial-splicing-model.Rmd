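---
title: "A spatial stochastic model of spliceosome assembly in a voxelized HeLa cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial stochastic model of spliceosome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceCell)
```

## The model

SpliceCell simulates two coupled processes of RNA splicing in a
spatially-resolved HeLa cell:

1. **snRNP particle formation** (the `table2` network): U1 and U2 snRNAs
   are transcribed in the nucleus, exported through nuclear pore
   complexes (NPCs), assembled with Gemin5 and the Sm protein ring in the
   cytoplasm, re-imported, and matured by particle-specific proteins in
   Cajal bodies and the nucleoplasm.
2. **Spliceosome assembly and splicing** (the `table3` network): pre-mRNA
   transcribed from active genes binds U1 (complex E), U2 (complex A) and
   the U4/U6.U5 tri-snRNP (complex B); activation releases U1 (B*) and
   splicing releases the mature mRNA together with U2 and tri-U.

The spatial substrate is a cubic lattice of subvolumes (default spacing
$\lambda = 64$ nm in an 18.432 µm box) in which every site carries one of
11 site types (extracellular space, plasma membrane, cytoplasm, nuclear
membrane, nucleoplasm, Cajal body, nuclear speckle, NPC, mitochondrion,
Golgi, ER). Dynamics follow the reaction–diffusion master equation
(RDME): molecule counts per subvolume change by nearest-neighbour
diffusion jumps with propensity $d^\alpha_\nu = D_\alpha/\lambda^2$ per
direction and by mass-action reactions with per-subvolume propensities
$a_r(\mathbf{x}_\nu)$, where bimolecular rate constants are converted as
$k / (N_A \lambda^3)$ per reactant pair (`bimolecularStochasticRate()`).

**Nuclear speckles** are realized purely as a transition-probability
bias: a jump from nucleoplasm into a speckle site is accepted with
probability $P_n$, the reverse with $P_s$. Detailed balance then gives
the equilibrium count fraction in speckles
$f = \rho V_s / (\rho V_s + V_n)$ with $\rho = P_n/P_s$
(`biasForLocalization()` inverts this). No binding partners inside
speckles are needed.

## Geometry builder

`buildCell()` voxelizes the cell by constructive solid geometry in depth
order (painter's algorithm; a site belongs to a shape iff its center
lies inside). Defaults follow the measured HeLa composition: a 8.9 µm
cell (3000 µm³), nucleus radius 3.7–5.3 µm (default 4.2), 0.128 µm
membranes, NPCs at 7/µm² (radius 0.08 µm) on a Fibonacci-sphere layout,
20 speckles of radius 0.35 µm, 4 Cajal bodies of radius 0.5 µm, ~2000
mitochondria (0.9 × 0.5 µm spherocylinders, ≈10% of cell volume, or
crossing 2.95-µm rods at matched total volume in "network" mode), a
five-sheet Golgi (cone ∩ concentric shells), and an ER grown by a
stochastic cellular automaton to 4.5% of the cell volume. Active genes
are placed 0–0.02 µm from speckle surfaces, round-robin over speckles.

Choices worth noting:

* **ER automaton.** Seeds on cytoplasm sites adjacent to the nuclear
  envelope dilate probabilistically into cytoplasm only, with acceptance
  decaying with radial distance (e-folding length half the
  envelope-to-membrane gap); growth stops exactly at the target count.
  This reproduces the stated properties (stochastic morphology, spanning
  growth, exact volume fraction) of the ER without prescribing a
  particular published automaton rule set.
* **NPC channels.** Pores are cylindrical channels through the envelope:
  membrane sites within $\max(0.08\,\mu m,\ 0.75\lambda)$ of the radial
  axis of each pore center. Below $0.75\lambda$ the voxelized channel
  can miss site centers and dead-end inside the membrane; the lower
  bound guarantees a face-connected column touching nucleoplasm on one
  side and cytoplasm on the other at every spacing. At coarse spacings
  this inflates the per-pore cross-section (pore *count* is unaffected),
  so absolute transport rates on coarse lattices are faster than at
  64 nm; contrast experiments compare arms on the same lattice.
* **Membrane thickness** is raised to one lattice spacing when
  $\lambda > 0.128$ µm; a thinner voxel shell would leak under
  6-adjacency.
* **Build order.** The nucleoplasm and both membranes are painted before
  the cytoplasmic organelles so that mitochondria/ER/Golgi can be
  confined to true cytoplasm sites; otherwise the later nucleus paint
  would silently erode their calibrated volume fractions.

The builder is also the package's data generator: every simulated
experiment constructs its own geometry in code (organelle placement
re-randomized per replicate), so tests need no stored fixtures. What it
does *not* emulate: chromatin, the nucleolus, cytoskeleton, deformable
or moving organelles, and sub-voxel structure. Passing tests therefore
validate the model's internal consistency and its published summary
statistics, not organelle-scale realism.

## Engines

* `runRDME()` advances the lattice state by operator splitting with a
  fixed timestep $\tau = \lambda^2/(6 D_{max})$ (`computeTimestep()`),
  which caps the per-direction jump probability at 1/6: a diffusion
  sweep of independent per-molecule jumps (site-type permeability
  rejects moves into disallowed sites; the speckle bias applies on
  boundary crossings), then an exact Gillespie sub-loop inside every
  subvolume that holds a reactant, with propensities refreshed after
  each event. In the $\tau \to 0$ limit this samples the same master
  equation as an exact next-subvolume scheme; the test suite verifies
  the single-subvolume limit against the exact SSA (two-sample KS), the
  Einstein relation for free diffusion, the speckle partition closed
  form for $\rho \in \{1,3,10,100\}$, exact conservation laws, and
  stability under $\tau$-halving.
* `runSSA()` is a direct-method Gillespie sampler over well-mixed
  compartments with first-order exchange; it is both the verification
  oracle and the fast surrogate for long runs. Pore transport
  coarse-grains to exchange-with-conversion at the series rate of
  diffusion-limited arrival $D A_{pores}/(\lambda V)$ and conversion
  $k_{npc} V_{pores}/V$, so flux scales with the pore count.
  Speckle exchange uses `deriveExchangeRates()`:
  $k_{in} = P_n D A/(\lambda V_n)$, $k_{out} = P_s D A/(\lambda V_s)$.
* `runCotxSplicing()` is an agent-based exact SSA for co-transcriptional
  splicing. Each gene initiates transcripts at `ktrans` (so the plain
  network's production rate is preserved: ~84 transcripts per 900 s over
  20 genes); the remaining intron–exon units of the 28,433-base template
  (8 introns × 3.4 Kb, 9 exons × 137 b) emerge sequentially at
  `8*ktrans` each, and every emerged intron assembles its spliceosome
  *independently*, drawing on shared U1/U2/tri-U pools in the
  transcript's compartment. Parallel intron processing is required by
  the biology (elongation continues while earlier introns are spliced)
  and by the magnitude of the published free-transcript count; a
  strictly serial one-intron-at-a-time reading leaves far more
  transcripts unbound. Mature mRNA is released once all introns are
  spliced.

Randomness: each engine uses a single xoshiro256** stream keyed by
`(seed, replicate)`. With single-threaded, fixed iteration order this
makes every trajectory bit-reproducible without a counter-based
generator.

## Parameters

All rate constants of the two networks are fixed to their published
values (see `reactionTable(particleFormationNetwork())` and
`reactionTable(splicingNetwork())`). Parameters the source does not pin
down, and the defaults chosen here:

* **Diffusion coefficients** (per-species, overridable): proteins and
  protein pools 9.35 µm²/s, snRNAs and their cytoplasmic intermediates
  1.0 µm²/s, snRNP particles/transcripts/spliceosomal complexes
  0.207 µm²/s. The two extremes reproduce the characteristic timesteps
  $7.3\times10^{-5}$ s (particle formation) and $3.3\times10^{-3}$ s
  (splicing) at $\lambda = 64$ nm.
* **Activation step.** The published activation constant (6×10⁴ M⁻¹s⁻¹)
  carries bimolecular units for a unimolecular conversion; it is
  implemented first-order at $6\times10^4/(N_A \lambda^3) = 0.38$ s⁻¹
  at 64 nm (the same conversion that maps the diffusion-limited binding
  constant 1.02×10⁸ to 646 s⁻¹ per pair per subvolume). With
  koff3 = 1.55 s⁻¹ roughly one in five B complexes activates per
  assembly; the others recycle through A.
* **Misassembly channel** (`misassemblyNetwork()`): premature binding of
  the particle-specific protein to the incomplete snRNA·Sm⁵ intermediate,
  irreversible, at the network's generic diffusion-limited constant
  1.02×10⁸ M⁻¹s⁻¹. The slower maturation constants konu1/konu2 would
  make misassembly a ~10% side channel and single-compartment assembly
  nearly harmless, contradicting the central published observation that
  misassembled products dominate; treating the error channel as
  diffusion-limited encounter is the reading consistent with that
  result. The rate is exposed (`misRate`) for sensitivity analysis.
* **snRNA genes**: 30 per snRNA species. Even so, total transcription
  over 30 s (~458 snRNAs) cannot reach the published product total
  (771 + 248); see Limitations.
* **tri-U abundance**: equal to the free U1 count (pre-formed pool).
* **Transition bias**: parameterized by the target localization through
  the partition formula with the *maximal-entry convention*
  ($P_n = 1$, $P_s = 1/\rho$). Only the ratio is identifiable from the
  partition; absolute acceptance probabilities are a free scale the
  source does not report. The convention makes speckle capture fast and
  recurrent, which matters for the gene-distance experiment (below).

## Scaled-down protocol

Published experiments are reproduced at reduced scale, 20 replicates
each (matching the published replication):

* nucleus-scale splicing runs (speckle anatomy, gene distance) on
  nucleus-only lattices at $\lambda = 128$ nm, full molecule counts;
* whole-cell particle-formation runs (pore counts, organelle removal)
  at $\lambda = 256$ nm with a count-scaling surrogate for the five
  abundant protein pools (counts × s, bimolecular k ÷ s, s = 0.005;
  minority species at full count). This preserves pseudo-first-order
  kinetics exactly; its cost is that the fastest (diffusion-limited)
  bindings saturate at the lattice encounter rate, so absolute yields
  are mildly compressed. Contrast experiments (±20% pores, organelle
  removal) share the distortion across arms, which is why percent
  changes are the reported observable.
* well-mixed (SSA / agent) surrogates for the 15-minute speckle sweeps,
  with compartment volumes measured from a built lattice.

## What matches and what does not

Run `scripts/acceptance.R` to recompute these numbers. At the study
conditions the package reproduces: the closed-form geometry anchors;
the 4.5% ER / 9–12% mitochondria / 1552-pore builder constraints; the
engine-level exactness checks; the mature-particle census of the
nucleus-only experiment (~250 at 30 s); the no-speckle free-transcript
count (~60 vs published 53.3); the sigmoidal speckle-enhancement curve
with its elongation-limited plateau (~60 spliced mRNA, free transcripts
collapsing, no enhancement at 5 nM, none at 0.1 nM below ~25%
localization); falling mRNA noise with rising localization; the
pore-count direction at every nuclear radius with no significant size
trend; the ~+28% yield gain on removing cytoplasmic organelles; and the
speckle-anatomy plateau by ~50 speckles.

Three published magnitudes are *not* reproduced and are reported as
computed:

* the misassembled-particle count (771): unreachable under the printed
  transcription budget (30 genes/species × 0.509 s⁻¹ × 30 s ≈ 458 total
  products), and the printed rate set makes correct assembly outcompete
  misassembly unless the error channel is diffusion-limited (see
  above); we obtain ≈220–280 misassembled versus ≈250 mature;
* the 250-fold enhancement at exactly 10% localization: the model's
  enhancement transition sits near 25% localization under the partition
  mapping used here; candidate causes are the unidentifiable absolute
  $P_n/P_s$ scale, unknown U2/tri-U abundances, and whether published
  "localization" counts free or total (complex-bound) U1;
* the factor-2 mRNA drop from d = 0.05 to 0.1 µm gene–speckle distance:
  with maximal-entry bias, capture is recurrent, so over 15 minutes
  essentially every transcript is spliced at either distance
  (ratio ≈ 1.0–1.1). A decisive first-encounter — hence a distance
  effect — requires small absolute $P_n$, which the source does not
  report.

## Limitations

No chromatin, nucleolus or cytoskeleton; no alternative splicing or
splice-site choice; no crowding beyond site-type exclusion; protein
pools are depletable but not replenished (quasi-steady-state over
15 min); coarse lattices inflate pore cross-sections; the count-scaling
surrogate compresses diffusion-limited rates. The two-compartment
surrogate's fidelity to full-lattice speckle kinetics is itself an
empirical question — the localization it realizes is verified against
the partition formula in the test suite, but transient capture effects
are not representable in it.
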