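# Example geometry configuration for `splicecell build`.
# Fields mirror the arguments of geometryConfig(); omitted fields use the
# documented defaults (full-size HeLa cell at 64 nm spacing).
spacing: 0.128        # lattice spacing, micrometres
cellRadius: 8.9
nuclearRadius: 4.2
nSpeckles: 20
speckleRadius: 0.35
nCajal: 4
cajalRadius: 0.5
nMito: 2000
erFraction: 0.045
nGenes: 20
seed: 1
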