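# Shared fixtures: all geometry is generated in code at test time.

# Small whole cell, coarse lattice: fast to build, all organelles present.
smallCellConfig <- function(...) {
  defaults <- list(edge = 6.4, spacing = 0.1, cellRadius = 2.9,
                   nuclearRadius = 1.4, membraneThickness = 0.2,
                   nMito = 30, mitoLength = 0.6, mitoDiameter = 0.3,
                   erFraction = 0.03, nSpeckles = 3, speckleRadius = 0.25,
                   nCajal = 1, cajalRadius = 0.3, golgiSheets = 2,
                   nGenes = 4, seed = 2)
  do.call(geometryConfig, utils::modifyList(defaults, list(...)))
}

smallCell <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(buildCell(smallCellConfig()))
    cache
  }
})

# Uniform one-type box (all nucleoplasm): free diffusion arena.
uniformBox <- function(n = 16, spacing = 0.1) {
  lat <- SpliceCell:::.emptyLattice(n * spacing, spacing, fill = "nucleoplasm")
  lat@config <- list(nuclearRadius = n * spacing / 2,
                     membraneThickness = spacing)
  lat
}

# Minimal network: given species/reaction data.frames.
adhocNetwork <- function(species, reactions, bias = NULL, variant = "test") {
  if (is.null(bias))
    bias <- data.frame(species = species$name, Pn = 1, Ps = 1)
  methods::new("ReactionNetwork", species = species, reactions = reactions,
               bias = bias, variant = variant, params = list())
}

spRow <- SpliceCell:::.sp
rxRow <- SpliceCell:::.rx

# 6-adjacency leak scan: count pairs of 6-adjacent sites with types a and b.
adjacencyCount <- function(lattice, typeA, typeB) {
  s <- lattice@sites
  a <- SpliceCell:::.SITE_TYPES[[typeA]]
  b <- SpliceCell:::.SITE_TYPES[[typeB]]
  d <- dim(s)
  n <- 0L
  pairAlong <- function(s1, s2) sum((s1 == a & s2 == b) | (s1 == b & s2 == a))
  n <- n + pairAlong(s[-d[1], , ], s[-1, , ])
  n <- n + pairAlong(s[, -d[2], ], s[, -1, ])
  n <- n + pairAlong(s[, , -d[3]], s[, , -1])
  n
}
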