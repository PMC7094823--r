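# SpliceCell

Spatial stochastic simulation of spliceosomal snRNP assembly and pre-mRNA
splicing in a voxelized HeLa cell.

Eukaryotic splicing machinery is built across compartments: U1/U2 snRNAs
are transcribed in the nucleus, exported through nuclear pore complexes,
assembled with Gemin5 and the Sm ring in the cytoplasm, re-imported and
matured in Cajal bodies; the finished particles concentrate in nuclear
speckles, membrane-less droplets where spliceosomes assemble on nascent
transcripts (E → A → B → B\* → spliced mRNA). SpliceCell is for
computational cell biologists who want to ask how this spatial
organization — pore counts, organelle crowding, speckle number/size/
partitioning, gene position — shapes splicing yield and noise.

The package provides:

* a **constructive-solid-geometry lattice builder** (`buildCell()`):
  11 site types stenciled in depth order (painter's algorithm) onto a
  cubic lattice (default spacing λ = 64 nm), with membranes, Fibonacci-
  layout nuclear pore channels, speckles, Cajal bodies, spherocylinder or
  network mitochondria, a cone-shell Golgi, and an ER grown by a seeded
  stochastic automaton to a target volume fraction;
* an **RDME engine** (`runRDME()`): fixed-timestep operator splitting of
  the reaction–diffusion master equation
  dP(**x**,t)/dt = **R**P + **D**P, with per-direction jump probability
  Dτ/λ² (τ = λ²/6D<sub>max</sub>), site-type permeability, and nuclear
  speckles realized as boundary-crossing acceptance probabilities
  P<sub>n</sub> (in) and P<sub>s</sub> (out), giving the equilibrium
  partition f = ρV<sub>s</sub>/(ρV<sub>s</sub>+V<sub>n</sub>),
  ρ = P<sub>n</sub>/P<sub>s</sub>;
* an exact **Gillespie engine over coupled compartments** (`runSSA()`),
  the verification oracle for the RDME and the fast surrogate for
  15-minute simulations, plus an agent-based exact sampler for
  co-transcriptional splicing (`runCotxSplicing()`);
* the two published reaction networks with all rate constants
  (`particleFormationNetwork()`, `splicingNetwork()`, the nucleus-only
  `misassemblyNetwork()` variant), and **experiment drivers** for the
  pore-count, misassembly, speckle-enhancement, speckle-anatomy,
  gene-distance and organelle-removal analyses;
* a thin command line (`inst/scripts/splicecell`): `build`, `run`,
  `ssa`, `experiment`, each writing a JSON run manifest.

## Worked example

Build the default cell on a reduced lattice and run the nucleus-only
misassembly experiment:

```r
library(SpliceCell)

lat <- buildCell(geometryConfig(spacing = 0.128, seed = 1))
constructionReport(lat)
#>           site_type site_count  volume_um3     fraction
#> 3         cytoplasm     982364 2060.166627 0.6979912123
#> 5       nucleoplasm     145178  304.460333 0.1031521597
#> 9      mitochondria     133954  280.921899 0.0951772610
#> 11               er      63334  132.821025 0.0450001989
#> ...
lat@config$npcCount
#> [1] 1552

ex <- runMisassemblyExperiment(nReps = 20, seed = 1)
ex$summary
#>        outcome  n   mean       sd         cv
#> 1 misassembled 20 211.70 16.84636 0.07957659
#> 2       mature 20 242.35 14.45601 0.05964932
```

The report shows the calibrated composition — ER at 4.50% of the cell
volume, mitochondria ≈ 9.5%, a 10.3% nucleus, 1552 pores on the 4.2-µm
envelope. The misassembly run places the whole particle-formation
pathway in the nucleus together with the premature-binding error
channel: after 30 s of biological time about 212 misassembled complexes
have formed alongside 242 correctly matured U1/U2 particles, the
quantitative argument for why snRNP assembly is split across
compartments (the ratio of error to correct product collapses to zero
once export/import separate the Sm-loading and protein-binding steps).

From a shell:

```sh
inst/scripts/splicecell build --config cell.yaml --out cell.lat.rds --report cell.tsv
inst/scripts/splicecell run --lattice cell.lat.rds --network table2 \
    --duration 30 --seed 1 --out traj.tsv
```

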