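## Reaction networks: snRNP particle formation (U1/U2), the nucleus-only
## misassembly variant, and spliceosome assembly/splicing.

#' Convert a molar concentration to a molecule count
#'
#' @param concentration molar concentration (M).
#' @param volume compartment volume in um^3 (typically measured from the
#'   lattice as site count x spacing^3).
#' @return integer count `round(c * N_A * V)`.
#' @export
concentrationToCount <- function(concentration, volume) {
  if (any(concentration < 0) || any(volume < 0))
    stop("concentration and volume must be >= 0")
  round(concentration * .AVOGADRO * volume * 1e-15)
}

#' Per-pair stochastic propensity of a bimolecular rate constant
#'
#' Converts a deterministic association constant (M^-1 s^-1) to the
#' per-reactant-pair propensity in a subvolume of edge `lambda`:
#' `k / (N_A * lambda^3)` with the subvolume volume in litres. The
#' per-subvolume propensity is then `a = (k / N_A lambda^3) * nA * nB`.
#'
#' @param k association rate constant (M^-1 s^-1).
#' @param lambda lattice spacing (um).
#' @return propensity per reactant pair per subvolume (s^-1).
#' @export
bimolecularStochasticRate <- function(k, lambda) {
  if (any(k < 0)) stop("rate constant must be >= 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  k / (.AVOGADRO * lambda^3 * 1e-15)
}

#' RDME timestep from the fastest diffusion coefficient
#'
#' `tau = lambda^2 / (6 D_max)`, which caps the per-direction jump
#' probability `D tau / lambda^2` at 1/6.
#'
#' @param lambda lattice spacing (um).
#' @param Dmax largest diffusion coefficient in the system (um^2/s).
#' @return timestep in seconds.
#' @export
computeTimestep <- function(lambda, Dmax) {
  if (any(Dmax <= 0)) stop("Dmax must be > 0")
  lambda^2 / (6 * Dmax)
}

## Default diffusion coefficients (um^2/s). Proteins and protein pools
## diffuse fastest; snRNAs and their cytoplasmic assembly intermediates are
## intermediate; ribonucleoprotein particles, transcripts and spliceosomal
## complexes are slowest. The two extremes reproduce the characteristic
## timesteps 7.3e-5 s (particle formation) and 3.3e-3 s (splicing) at
## lambda = 64 nm.
.D_PROTEIN <- 9.35
.D_RNA <- 1.0
.D_PARTICLE <- 0.207

.rateParamsTable2 <- function() list(
  ktrans1 = 0.285, ktrans2 = 0.224, knpc = 2e4,
  konG = 1.02e8, koffG = 3.05,
  kS1 = 5.9e7, kS2 = 1.18e7,
  kon2 = 1.39e8, koff2 = 2.78,
  konu1 = 1.22e7, koffu1 = 4.8e-4,
  konu2 = 0.24e7, koffu2 = 4.8e-4)

.rateParamsTable3 <- function() list(
  ktrans = 4.7e-3,
  kon1 = 4.66e7, koff1 = 1.57,
  kon2 = 8.8e7, koff2 = 0.062,
  kon3 = 4.66e7, koff3 = 1.55,
  kact = 6e4, kspl = 0.067,
  knpc = 2e4)

.sp <- function(name, D, allowed, pool = FALSE, init_mode = "count",
                init_value = 0, init_where = NA_character_) {
  data.frame(name = name, D = D, allowed = .joinNames(allowed), pool = pool,
             init_mode = init_mode, init_value = init_value,
             init_where = init_where, stringsAsFactors = FALSE)
}
.rx <- function(name, r1, r2, products, rate, units, where) {
  data.frame(name = name, r1 = r1, r2 = r2,
             products = .joinNames(products), rate = rate, units = units,
             where = .joinNames(where), stringsAsFactors = FALSE)
}

.NUC <- c("nucleoplasm", "cajal", "speckle", "npc")
.NUCI <- c("nucleoplasm", "cajal", "speckle")  # nuclear interior, no pores
.CYT <- c("cytoplasm", "npc")

#' Particle-formation reaction network
#'
#' The 20-reaction network for U1/U2 snRNP biogenesis: nuclear snRNA
#' transcription, export through nuclear pores, cytoplasmic Gemin5 binding,
#' RNP exchange onto the pre-assembled Sm5 ring, Sm2 completion, re-import,
#' and Cajal/nuclear maturation by the particle-specific proteins.
#'
#' Initial conditions: `nGenes` snRNA gene sites per species in the
#' nucleoplasm; G5/Sm5/Sm2 at 0.61 uM in the cytoplasm; U1prot at 0.89 uM
#' and U2prot at 0.56 uM in the nucleoplasm (depletable, not replenished).
#'
#' @param nGenes active snRNA genes per snRNA species (default 30).
#' @param params optional list overriding any rate constant (see
#'   `reactionTable()` for names).
#' @return a [ReactionNetwork-class].
#' @export
particleFormationNetwork <- function(nGenes = 30, params = list()) {
  p <- utils::modifyList(.rateParamsTable2(), params)
  species <- rbind(
    .sp("D_U1", 0, "nucleoplasm", init_mode = "count", init_value = nGenes,
        init_where = "nucleoplasm"),
    .sp("D_U2", 0, "nucleoplasm", init_mode = "count", init_value = nGenes,
        init_where = "nucleoplasm"),
    .sp("U1snRNA_nuc", .D_RNA, .NUC),
    .sp("U2snRNA_nuc", .D_RNA, .NUC),
    .sp("U1snRNA_cyt", .D_RNA, .CYT),
    .sp("U2snRNA_cyt", .D_RNA, .CYT),
    .sp("U1snRNA_G5", .D_RNA, .CYT),
    .sp("U2snRNA_G5", .D_RNA, .CYT),
    .sp("U1snRNA_Sm5", .D_RNA, .CYT),
    .sp("U2snRNA_Sm5", .D_RNA, .CYT),
    .sp("U1snRNA_Sm7", .D_RNA, .CYT),
    .sp("U2snRNA_Sm7", .D_RNA, .CYT),
    .sp("U1snRNA_Sm7_nuc", .D_RNA, .NUC),
    .sp("U2snRNA_Sm7_nuc", .D_RNA, .NUC),
    .sp("U1snRNP", .D_PARTICLE, .NUCI),
    .sp("U2snRNP", .D_PARTICLE, .NUCI),
    .sp("G5", .D_PROTEIN, "cytoplasm", pool = TRUE, init_mode = "conc",
        init_value = 0.61e-6, init_where = "cytoplasm"),
    .sp("Sm5", .D_PROTEIN, "cytoplasm", pool = TRUE, init_mode = "conc",
        init_value = 0.61e-6, init_where = "cytoplasm"),
    .sp("Sm2", .D_PROTEIN, "cytoplasm", pool = TRUE, init_mode = "conc",
        init_value = 0.61e-6, init_where = "cytoplasm"),
    .sp("U1prot", .D_PROTEIN, .NUCI, pool = TRUE, init_mode = "conc",
        init_value = 0.89e-6, init_where = "nucleoplasm"),
    .sp("U2prot", .D_PROTEIN, .NUCI, pool = TRUE, init_mode = "conc",
        init_value = 0.56e-6, init_where = "nucleoplasm"))
  reactions <- rbind(
    .rx("transcription_U1", "D_U1", NA, c("D_U1", "U1snRNA_nuc"),
        p$ktrans1, "s-1", "nucleoplasm"),
    .rx("transcription_U2", "D_U2", NA, c("D_U2", "U2snRNA_nuc"),
        p$ktrans2, "s-1", "nucleoplasm"),
    .rx("export_U1", "U1snRNA_nuc", NA, "U1snRNA_cyt", p$knpc, "s-1", "npc"),
    .rx("export_U2", "U2snRNA_nuc", NA, "U2snRNA_cyt", p$knpc, "s-1", "npc"),
    .rx("bindG5_U1", "U1snRNA_cyt", "G5", "U1snRNA_G5", p$konG, "M-1s-1",
        "cytoplasm"),
    .rx("bindG5_U2", "U2snRNA_cyt", "G5", "U2snRNA_G5", p$konG, "M-1s-1",
        "cytoplasm"),
    .rx("unbindG5_U1", "U1snRNA_G5", NA, c("U1snRNA_cyt", "G5"), p$koffG,
        "s-1", "cytoplasm"),
    .rx("unbindG5_U2", "U2snRNA_G5", NA, c("U2snRNA_cyt", "G5"), p$koffG,
        "s-1", "cytoplasm"),
    .rx("rnpExchange_U1", "U1snRNA_G5", "Sm5", c("U1snRNA_Sm5", "G5"),
        p$kS1, "M-1s-1", "cytoplasm"),
    .rx("rnpExchange_U2", "U2snRNA_G5", "Sm5", c("U2snRNA_Sm5", "G5"),
        p$kS2, "M-1s-1", "cytoplasm"),
    .rx("bindSm2_U1", "U1snRNA_Sm5", "Sm2", "U1snRNA_Sm7", p$kon2,
        "M-1s-1", "cytoplasm"),
    .rx("bindSm2_U2", "U2snRNA_Sm5", "Sm2", "U2snRNA_Sm7", p$kon2,
        "M-1s-1", "cytoplasm"),
    .rx("unbindSm2_U1", "U1snRNA_Sm7", NA, c("U1snRNA_Sm5", "Sm2"),
        p$koff2, "s-1", "cytoplasm"),
    .rx("unbindSm2_U2", "U2snRNA_Sm7", NA, c("U2snRNA_Sm5", "Sm2"),
        p$koff2, "s-1", "cytoplasm"),
    .rx("import_U1", "U1snRNA_Sm7", NA, "U1snRNA_Sm7_nuc", p$knpc, "s-1",
        "npc"),
    .rx("import_U2", "U2snRNA_Sm7", NA, "U2snRNA_Sm7_nuc", p$knpc, "s-1",
        "npc"),
    .rx("mature_U1", "U1snRNA_Sm7_nuc", "U1prot", "U1snRNP", p$konu1,
        "M-1s-1", c("cajal", "nucleoplasm")),
    .rx("unmature_U1", "U1snRNP", NA, c("U1snRNA_Sm7_nuc", "U1prot"),
        p$koffu1, "s-1", c("cajal", "nucleoplasm")),
    .rx("mature_U2", "U2snRNA_Sm7_nuc", "U2prot", "U2snRNP", p$konu2,
        "M-1s-1", c("cajal", "nucleoplasm")),
    .rx("unmature_U2", "U2snRNP", NA, c("U2snRNA_Sm7_nuc", "U2prot"),
        p$koffu2, "s-1", c("cajal", "nucleoplasm")))
  bias <- data.frame(species = species$name, Pn = 1, Ps = 1)
  methods::new("ReactionNetwork", species = species, reactions = reactions,
               bias = bias, variant = "table2",
               params = c(p, list(nGenes = nGenes)))
}

#' Nucleus-only misassembly network variant
#'
#' The particle-formation network with every compartment restriction
#' replaced by the nuclear interior (no pore transport barrier), plus two
#' irreversible misassembly channels in which the particle-specific protein
#' binds the incomplete Sm5 intermediate:
#' `U1(2)snRNA.Sm5 + U1(2)prot -> misassembled_U1(2)`.
#' The misassembled species are terminal. The channel rate defaults to the
#' network's generic diffusion-limited binding constant (1.02e8 M^-1 s^-1,
#' the same class as Gemin5 binding): premature binding is a
#' diffusion-limited encounter, which is what makes single-compartment
#' assembly error-prone.
#'
#' @param nGenes active snRNA genes per species.
#' @param misRate misassembly association constant (M^-1 s^-1). Set to 0 to
#'   recover nucleus-only correct assembly.
#' @param params rate overrides as in [particleFormationNetwork()].
#' @return a [ReactionNetwork-class].
#' @export
misassemblyNetwork <- function(nGenes = 30, misRate = 1.02e8,
                               params = list()) {
  if (misRate < 0) stop("misRate must be >= 0")
  net <- particleFormationNetwork(nGenes, params)
  sp <- net@species
  sp$allowed <- .joinNames(.NUCI)
  sp$allowed[sp$name %in% c("D_U1", "D_U2")] <- "nucleoplasm"
  sp$init_where[!is.na(sp$init_where)] <- "nucleoplasm"
  sp <- rbind(sp,
              .sp("misassembled_U1", .D_PARTICLE, .NUCI),
              .sp("misassembled_U2", .D_PARTICLE, .NUCI))
  rx <- net@reactions
  rx$where <- .joinNames(.NUCI)
  rx$where[rx$name %in% c("transcription_U1", "transcription_U2")] <-
    "nucleoplasm"
  rx <- rbind(rx,
    .rx("misassembly_U1", "U1snRNA_Sm5", "U1prot", "misassembled_U1",
        misRate, "M-1s-1", .NUCI),
    .rx("misassembly_U2", "U2snRNA_Sm5", "U2prot", "misassembled_U2",
        misRate, "M-1s-1", .NUCI))
  bias <- data.frame(species = sp$name, Pn = 1, Ps = 1)
  methods::new("ReactionNetwork", species = sp, reactions = rx, bias = bias,
               variant = "table2_nucleus_only",
               params = c(net@params, list(misRate = misRate)))
}

#' Spliceosome assembly and splicing network
#'
#' Pre-mRNA transcription from active genes, stepwise spliceosome assembly
#' (U1 + pre-mRNA -> E; E + U2 -> A; A + triU -> B), activation
#' (B -> B* + U1) and splicing (B* -> mRNA + triU + U2), all restricted to
#' nucleoplasm and speckles. The printed activation constant carries
#' bimolecular units for a unimolecular conversion; it is implemented as a
#' fast first-order step with default rate `6e4 / (N_A (64 nm)^3)`
#' (about 380 s^-1), exposed via `params$kactFirstOrder`. Mature mRNA may
#' cross pore sites (rate knpc) so cytoplasmic mRNA is observable.
#'
#' The co-transcriptional variant (tag "table3_cotx") is simulated by
#' [runCotxSplicing()], which models each transcript as a chain of
#' `nIntrons` intron-exon units emerging at per-unit rate
#' `8 * ktrans` and spliced independently.
#'
#' @param nGenes number of active genes (default 20).
#' @param particleConc free U1/U2/triU concentration in molar (default
#'   1e-9); counts are derived from the measured nucleoplasm volume.
#' @param localization target fraction of splicing particles in speckles;
#'   sets the transition bias via the partition formula (0 = no bias).
#' @param speckleVolume,nucleoplasmVolume volumes (um^3) used to convert
#'   `localization` into Pn/Ps; measured from a lattice when used
#'   spatially.
#' @param cotranscriptional flag recorded in the variant tag.
#' @param params rate overrides.
#' @return a [ReactionNetwork-class].
#' @export
splicingNetwork <- function(nGenes = 20, particleConc = 1e-9,
                            localization = 0,
                            speckleVolume = NULL, nucleoplasmVolume = NULL,
                            cotranscriptional = FALSE, params = list()) {
  p <- utils::modifyList(.rateParamsTable3(), params)
  if (is.null(p$kactFirstOrder))
    p$kactFirstOrder <- bimolecularStochasticRate(p$kact, 0.064)
  SN <- c("nucleoplasm", "speckle")
  species <- rbind(
    .sp("D_gene", 0, "nucleoplasm", init_mode = "count",
        init_value = nGenes, init_where = "genes"),
    .sp("preMRNA", .D_PARTICLE, SN),
    .sp("U1", .D_PARTICLE, SN, pool = TRUE, init_mode = "conc",
        init_value = particleConc, init_where = "nucleoplasm"),
    .sp("U2", .D_PARTICLE, SN, pool = TRUE, init_mode = "conc",
        init_value = particleConc, init_where = "nucleoplasm"),
    .sp("triU", .D_PARTICLE, SN, pool = TRUE, init_mode = "conc",
        init_value = particleConc, init_where = "nucleoplasm"),
    .sp("complexE", .D_PARTICLE, SN),
    .sp("complexA", .D_PARTICLE, SN),
    .sp("complexB", .D_PARTICLE, SN),
    .sp("complexBstar", .D_PARTICLE, SN),
    .sp("mRNA_nuc", .D_PARTICLE, c(SN, "npc")),
    .sp("mRNA_cyt", .D_PARTICLE, c("cytoplasm", "npc")))
  reactions <- rbind(
    .rx("transcription", "D_gene", NA, c("D_gene", "preMRNA"), p$ktrans,
        "s-1", "nucleoplasm"),
    .rx("bindU1", "U1", "preMRNA", "complexE", p$kon1, "M-1s-1", SN),
    .rx("unbindU1", "complexE", NA, c("U1", "preMRNA"), p$koff1, "s-1", SN),
    .rx("bindU2", "complexE", "U2", "complexA", p$kon2, "M-1s-1", SN),
    .rx("unbindU2", "complexA", NA, c("complexE", "U2"), p$koff2, "s-1", SN),
    .rx("bindTriU", "complexA", "triU", "complexB", p$kon3, "M-1s-1", SN),
    .rx("unbindTriU", "complexB", NA, c("complexA", "triU"), p$koff3,
        "s-1", SN),
    .rx("activate", "complexB", NA, c("complexBstar", "U1"),
        p$kactFirstOrder, "s-1", SN),
    .rx("splice", "complexBstar", NA, c("mRNA_nuc", "triU", "U2"), p$kspl,
        "s-1", SN),
    .rx("export_mRNA", "mRNA_nuc", NA, "mRNA_cyt", p$knpc, "s-1", "npc"))
  biased <- c("U1", "U2", "triU", "preMRNA", "complexE", "complexA",
              "complexB", "complexBstar")
  bias <- data.frame(species = species$name, Pn = 1, Ps = 1)
  if (localization > 0) {
    if (is.null(speckleVolume) || is.null(nucleoplasmVolume))
      stop("speckleVolume and nucleoplasmVolume are needed to set the bias")
    ps <- biasForLocalization(localization, speckleVolume,
                              nucleoplasmVolume)
    bias$Pn[bias$species %in% biased] <- ps[["Pn"]]
    bias$Ps[bias$species %in% biased] <- ps[["Ps"]]
  }
  methods::new("ReactionNetwork", species = species, reactions = reactions,
               bias = bias,
               variant = if (cotranscriptional) "table3_cotx" else "table3",
               params = c(p, list(nGenes = nGenes,
                                  particleConc = particleConc,
                                  localization = localization)))
}

#' Transition bias for a target speckle localization
#'
#' Inverts the equilibrium partition
#' `f = rho V_s / (rho V_s + V_n)` with `rho = Pn/Ps` and returns
#' `c(Pn, Ps)` with the larger of the two set to 1.
#'
#' @param f target localized fraction in (0, 1).
#' @param speckleVolume,nucleoplasmVolume volumes (um^3).
#' @return named numeric `c(Pn =, Ps =)`.
#' @export
biasForLocalization <- function(f, speckleVolume, nucleoplasmVolume) {
  if (f <= 0 || f >= 1) stop("target localization must be in (0, 1)")
  rho <- f / (1 - f) * nucleoplasmVolume / speckleVolume
  if (rho >= 1) c(Pn = 1, Ps = 1 / rho) else c(Pn = rho, Ps = 1)
}

#' Built-in network presets
#'
#' @param name one of "table2", "table2_nucleus_only", "table3",
#'   "table3_cotx".
#' @param ... passed to the corresponding builder.
#' @return a [ReactionNetwork-class].
#' @export
networkPreset <- function(name = c("table2", "table2_nucleus_only",
                                   "table3", "table3_cotx"), ...) {
  name <- match.arg(name)
  switch(name,
         table2 = particleFormationNetwork(...),
         table2_nucleus_only = misassemblyNetwork(...),
         table3 = splicingNetwork(...),
         table3_cotx = splicingNetwork(..., cotranscriptional = TRUE))
}

#' Total gene length of the co-transcriptional splicing template
#'
#' `nIntrons` introns of `intronLength` bases with `nIntrons + 1` exons of
#' `exonLength` bases.
#'
#' @param nIntrons,intronLength,exonLength defaults 8, 3400, 137.
#' @return length in bases (28,433 for the defaults, i.e. ~28 Kb).
#' @export
geneLengthBases <- function(nIntrons = 8, intronLength = 3400,
                            exonLength = 137) {
  nIntrons * intronLength + (nIntrons + 1) * exonLength
}

## ---- YAML round trip --------------------------------------------------

#' Write / read a network definition
#'
#' Round-trips the species, reactions (with rate units and compartment
#' restrictions) and transition bias through a YAML document so networks
#' can be edited without code changes.
#'
#' @param network a [ReactionNetwork-class].
#' @param path file path.
#' @return `readNetwork` returns the reconstructed network.
#' @export
writeNetwork <- function(network, path) {
  doc <- list(
    format = "SpliceCell-network/1",
    variant = network@variant,
    params = network@params,
    species = lapply(seq_len(nrow(network@species)), function(i)
      as.list(network@species[i, ])),
    reactions = lapply(seq_len(nrow(network@reactions)), function(i)
      as.list(network@reactions[i, ])),
    bias = lapply(seq_len(nrow(network@bias)), function(i)
      as.list(network@bias[i, ])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format) || !startsWith(doc$format, "SpliceCell-network/"))
    stop("not a SpliceCell network file: ", path)
  bindRows <- function(lst) do.call(rbind, lapply(lst, function(x) {
    as.data.frame(lapply(x, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  methods::new("ReactionNetwork",
               species = bindRows(doc$species),
               reactions = bindRows(doc$reactions),
               bias = bindRows(doc$bias),
               variant = doc$variant,
               params = doc$params)
}
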