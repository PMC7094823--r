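## Well-mixed compartment engine: exact direct-method SSA with first-order
## exchange; the verification oracle for the RDME and the fast surrogate for
## long simulations.

#' Construct a compartment model
#'
#' @param compartments data.frame with columns name, volume (um^3),
#'   site_types (comma-separated lattice site types the compartment
#'   stands for).
#' @param exchange data.frame with columns species, from, to, rate
#'   (s^-1 per molecule) and optional convert_to (species the molecule
#'   becomes on arrival, for pore transport); may be empty.
#' @param network a [ReactionNetwork-class].
#' @return a [CompartmentModel-class].
#' @export
compartmentModel <- function(compartments, exchange = NULL, network) {
  if (is.null(exchange))
    exchange <- data.frame(species = character(0), from = character(0),
                           to = character(0), rate = numeric(0),
                           convert_to = character(0))
  if (is.null(exchange$convert_to))
    exchange$convert_to <- exchange$species
  methods::new("CompartmentModel", compartments = compartments,
               exchange = exchange, network = network)
}

#' First-order exchange rates for speckle partitioning
#'
#' Coarse-grains the lattice diffusion operator across the
#' nucleoplasm/speckle interface into first-order exchange:
#' `k_in = Pn D A / (lambda V_n)` and `k_out = Ps D A / (lambda V_s)`
#' with `A` the total speckle surface area. The equilibrium concentration
#' ratio is then `c_s / c_n = Pn / Ps` and the equilibrium count fraction
#' is `rho V_s / (rho V_s + V_n)` with `rho = Pn/Ps`.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param Pn,Ps transition probabilities.
#' @param area total interface area (um^2).
#' @param lambda lattice spacing (um).
#' @param nucleoplasmVolume,speckleVolume volumes (um^3).
#' @return named numeric `c(kIn =, kOut =)` in s^-1 per molecule.
#' @export
deriveExchangeRates <- function(D, Pn, Ps, area, lambda,
                                nucleoplasmVolume, speckleVolume) {
  if (nucleoplasmVolume <= 0 || speckleVolume <= 0)
    stop("compartment volumes must be > 0")
  c(kIn = Pn * D * area / (lambda * nucleoplasmVolume),
    kOut = Ps * D * area / (lambda * speckleVolume))
}

.compSiteTypes <- function(model) {
  lapply(model@compartments$site_types, .splitNames)
}

#' Run the exact Gillespie SSA on a compartment model
#'
#' Direct-method SSA; bimolecular propensities use `k / (N_A V)` with the
#' compartment volume. Exchange channels move (and optionally convert)
#' one molecule at a time.
#'
#' @param model a [CompartmentModel-class].
#' @param duration seconds; `recordInterval` recording step (default: only
#'   endpoints).
#' @param seed,replicate integers; the pair keys the random stream.
#' @param initOverride optional named list: species -> named vector of
#'   counts per compartment, overriding the network's initial conditions.
#' @return a [Trajectory-class].
#' @export
runSSA <- function(model, duration, recordInterval = NULL, seed = 1L,
                   replicate = 1L, initOverride = NULL) {
  net <- model@network
  sp <- net@species
  rx <- net@reactions
  cmp <- model@compartments
  nSp <- nrow(sp)
  nC <- nrow(cmp)
  stIdx <- function(si, ci) (ci - 1L) * nSp + si  # 1-based state index
  compTypes <- .compSiteTypes(model)

  ## initial state
  init <- integer(nSp * nC)
  for (i in seq_len(nSp)) {
    if (is.na(sp$init_where[i]) || sp$init_value[i] <= 0) next
    where <- if (identical(sp$init_where[i], "genes")) "nucleoplasm"
             else sp$init_where[i]
    ci <- which(vapply(compTypes, function(tt) where %in% tt, logical(1)))
    if (length(ci) == 0)
      stop("no compartment hosts site type '", where, "'")
    ci <- ci[1]
    n <- if (sp$init_mode[i] == "conc")
      concentrationToCount(sp$init_value[i], cmp$volume[ci])
    else round(sp$init_value[i])
    init[stIdx(i, ci)] <- n
  }
  if (!is.null(initOverride)) {
    for (nm in names(initOverride)) {
      si <- match(nm, sp$name)
      if (is.na(si)) stop("initOverride names unknown species ", nm)
      v <- initOverride[[nm]]
      for (cn in names(v)) {
        ci <- match(cn, cmp$name)
        if (is.na(ci)) stop("initOverride names unknown compartment ", cn)
        init[stIdx(si, ci)] <- round(v[[cn]])
      }
    }
  }

  ## channels
  chOrder <- integer(0); chR1 <- integer(0); chR2 <- integer(0)
  chRate <- numeric(0); chProd <- list(); chName <- character(0)
  addCh <- function(order, r1, r2, prods, rate, name) {
    chOrder[[length(chOrder) + 1L]] <<- order
    chR1[[length(chR1) + 1L]] <<- r1
    chR2[[length(chR2) + 1L]] <<- r2
    chProd[[length(chProd) + 1L]] <<- as.integer(prods)
    chRate[[length(chRate) + 1L]] <<- rate
    chName[[length(chName) + 1L]] <<- name
  }
  for (i in seq_len(nrow(rx))) {
    where <- .splitNames(rx$where[i])
    for (ci in seq_len(nC)) {
      if (!any(where %in% compTypes[[ci]])) next
      rate <- if (rx$units[i] == "M-1s-1")
        rx$rate[i] / (.AVOGADRO * cmp$volume[ci] * 1e-15) else rx$rate[i]
      r1 <- stIdx(match(rx$r1[i], sp$name), ci) - 1L
      r2 <- if (is.na(rx$r2[i])) -1L
            else stIdx(match(rx$r2[i], sp$name), ci) - 1L
      prods <- stIdx(match(.splitNames(rx$products[i]), sp$name), ci) - 1L
      addCh(if (r2 >= 0) 2L else 1L, r1, r2, prods, rate,
            sprintf("%s@%s", rx$name[i], cmp$name[ci]))
    }
  }
  ex <- model@exchange
  for (i in seq_len(nrow(ex))) {
    si <- match(ex$species[i], sp$name)
    so <- match(ex$convert_to[i] %||% ex$species[i], sp$name)
    ci <- match(ex$from[i], cmp$name)
    co <- match(ex$to[i], cmp$name)
    if (anyNA(c(si, so, ci, co)))
      stop("exchange row ", i, " references unknown species/compartment")
    addCh(1L, stIdx(si, ci) - 1L, -1L, stIdx(so, co) - 1L, ex$rate[i],
          sprintf("x_%s_%s_to_%s", ex$species[i], ex$from[i], ex$to[i]))
  }

  if (is.null(recordInterval)) recordInterval <- duration
  res <- ssa_core(init = init,
                  ch_order = as.integer(chOrder),
                  ch_r1 = as.integer(chR1), ch_r2 = as.integer(chR2),
                  ch_products = chProd, ch_rate = chRate,
                  duration = duration, record_interval = recordInterval,
                  seed = as.integer(seed), stream = as.integer(replicate))

  nT <- length(res$times)
  counts <- array(res$counts, dim = c(nSp, nC, nT))
  fs <- rep(-1, nSp)
  for (i in seq_len(nSp)) {
    v <- res$first_seen[stIdx(i, seq_len(nC))]
    v <- v[v >= 0]
    if (length(v)) fs[i] <- min(v)
  }
  methods::new(
    "Trajectory",
    times = as.numeric(res$times), counts = counts,
    speciesNames = sp$name, compartmentNames = cmp$name,
    tally = setNames(as.numeric(res$tally), chName),
    firstSeen = setNames(fs, sp$name),
    metadata = list(engine = "ssa", seed = seed, replicate = replicate,
                    variant = net@variant, nEvents = res$n_events))
}

## ---- surrogate model builders ----------------------------------------

.sphereVol <- function(r) 4 / 3 * pi * r^3

#' Geometry summary for surrogate models
#'
#' Compartment volumes and interface areas, measured from a built lattice
#' when one is given, otherwise from the configured spheres.
#'
#' @param lattice a [SiteLattice-class], or NULL.
#' @param config a [geometryConfig()] used when `lattice` is NULL.
#' @return list with volumes (um^3: nucleus, cytoplasm, speckle total),
#'   poreArea (um^2), speckleArea (um^2), lambda, npcCount.
#' @export
geometrySummary <- function(lattice = NULL, config = geometryConfig()) {
  if (!is.null(lattice)) {
    cfg <- lattice@config
    tab <- siteTypeCounts(lattice)
    v <- lattice@spacing^3
    nspk <- cfg$nSpeckles %||% 0
    rs <- cfg$speckleRadiusRealized %||% cfg$speckleRadius
    list(
      nucleusVolume = unname((tab[["nucleoplasm"]] + tab[["cajal"]]) * v),
      cytoplasmVolume = unname(tab[["cytoplasm"]] * v),
      speckleVolume = unname(tab[["speckle"]] * v),
      poreArea = unname(tab[["npc"]] * v /
                          max(cfg$membraneThickness, lattice@spacing)),
      speckleArea = nspk * 4 * pi * rs^2,
      lambda = lattice@spacing,
      npcCount = cfg$npcCount %||% NA_integer_)
  } else {
    cfg <- config
    rn <- cfg$nuclearRadius
    nspk <- cfg$nSpeckles
    rs <- if (!is.null(cfg$speckleTotalFraction))
      (3 * cfg$speckleTotalFraction * .sphereVol(rn) / (4 * pi * nspk))^(1 / 3)
    else cfg$speckleRadius
    vspk <- nspk * .sphereVol(rs)
    vcaj <- cfg$nCajal * .sphereVol(cfg$cajalRadius)
    npc <- round(cfg$npcDensity * 4 * pi * rn^2)
    list(
      nucleusVolume = .sphereVol(rn) - vspk,
      cytoplasmVolume = .sphereVol(cfg$cellRadius) -
        .sphereVol(rn + cfg$membraneThickness) -
        (cfg$erFraction + 0.106) * .sphereVol(cfg$cellRadius),
      speckleVolume = vspk,
      poreArea = npc * pi * cfg$npcRadius^2,
      speckleArea = nspk * 4 * pi * rs^2,
      lambda = cfg$spacing,
      npcCount = npc)
  }
}

#' Well-mixed surrogate of the particle-formation system
#'
#' Two compartments (nucleus, cytoplasm). Pore transport becomes
#' first-order exchange-with-conversion at the series rate of
#' diffusion-limited arrival `D A_pore / (lambda V_donor)` and conversion
#' `knpc V_pore / V_donor`, so the flux scales with the pore count.
#'
#' @param network a table2 [ReactionNetwork-class].
#' @param geom a [geometrySummary()].
#' @param npcScale multiplier on the pore count (0.8 / 1.0 / 1.2 in the
#'   pore-count experiment).
#' @return a [CompartmentModel-class].
#' @export
formationCompartmentModel <- function(network = particleFormationNetwork(),
                                      geom = geometrySummary(),
                                      npcScale = 1) {
  cmp <- data.frame(
    name = c("nucleus", "cytoplasm"),
    volume = c(geom$nucleusVolume, geom$cytoplasmVolume),
    site_types = c(.joinNames(c("nucleoplasm", "cajal", "speckle")),
                   "cytoplasm"))
  A <- geom$poreArea * npcScale
  lam <- geom$lambda
  knpc <- network@params$knpc
  Vpore <- A * lam  # effective pore volume
  series <- function(D, Vdonor) {
    if (A <= 0) return(0)
    ka <- D * A / (lam * Vdonor)
    kc <- knpc * Vpore / Vdonor
    1 / (1 / ka + 1 / kc)
  }
  Drna <- network@species$D[match("U1snRNA_nuc", network@species$name)]
  ex <- rbind(
    data.frame(species = "U1snRNA_nuc", from = "nucleus", to = "cytoplasm",
               rate = series(Drna, geom$nucleusVolume),
               convert_to = "U1snRNA_cyt"),
    data.frame(species = "U2snRNA_nuc", from = "nucleus", to = "cytoplasm",
               rate = series(Drna, geom$nucleusVolume),
               convert_to = "U2snRNA_cyt"),
    data.frame(species = "U1snRNA_Sm7", from = "cytoplasm", to = "nucleus",
               rate = series(Drna, geom$cytoplasmVolume),
               convert_to = "U1snRNA_Sm7_nuc"),
    data.frame(species = "U2snRNA_Sm7", from = "cytoplasm", to = "nucleus",
               rate = series(Drna, geom$cytoplasmVolume),
               convert_to = "U2snRNA_Sm7_nuc"))
  compartmentModel(cmp, ex, network)
}

#' Single-compartment model of the nucleus-only misassembly system
#'
#' @param network a [misassemblyNetwork()].
#' @param nuclearVolume nucleus volume in um^3 (default: the 4.2-um
#'   nucleus).
#' @return a [CompartmentModel-class].
#' @export
misassemblyCompartmentModel <- function(network = misassemblyNetwork(),
                                        nuclearVolume = .sphereVol(4.2)) {
  cmp <- data.frame(name = "nucleus", volume = nuclearVolume,
                    site_types = .joinNames(c("nucleoplasm", "cajal",
                                              "speckle")))
  compartmentModel(cmp, NULL, network)
}
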