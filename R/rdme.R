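## R-side driver for the lattice RDME engine.

.allowedMask <- function(allowed) {
  codes <- .SITE_TYPES[.splitNames(allowed)]
  if (anyNA(codes)) stop("unknown site type in allowed set: ", allowed)
  sum(bitwShiftL(1L, codes))
}

.linearIndex <- function(coord, d) {
  coord[, 1] + (coord[, 2] - 1L) * d[1] + (coord[, 3] - 1L) * d[1] * d[2]
}

#' Run a spatial stochastic (RDME) simulation
#'
#' Advances the state by operator splitting with timestep `tau`: a
#' diffusion sweep (independent per-molecule jumps, per-direction
#' probability `D tau / lambda^2`, site-type permeability and speckle
#' transition bias) followed by an exact Gillespie sub-loop within every
#' occupied subvolume. Fully reproducible from `(seed, replicate)`.
#'
#' Initial molecules are placed uniformly at random over the lattice sites
#' of each species' initial region (gene species go to the lattice's gene
#' positions); concentrations are converted to counts with the measured
#' region volume.
#'
#' @param lattice a [SiteLattice-class].
#' @param network a [ReactionNetwork-class].
#' @param duration biological time to simulate (s).
#' @param tau timestep (s); default `computeTimestep(spacing, max(D))`.
#' @param recordInterval recording interval (s).
#' @param seed,replicate integers keying the random stream and the
#'   placement randomization.
#' @param countScale scale factor for the counts of pool species
#'   (bimolecular rates of reactions consuming a pool species are divided
#'   by the same factor, preserving pseudo-first-order kinetics); the
#'   scaled-down surrogate for whole-cell runs.
#' @param trackSpecies optional character vector of species whose molecule
#'   positions are recorded at every recording time.
#' @return a [Trajectory-class] whose compartments are the 11 site types.
#' @export
runRDME <- function(lattice, network, duration, tau = NULL,
                    recordInterval = NULL, seed = 1L, replicate = 1L,
                    countScale = 1, trackSpecies = NULL) {
  sp <- network@species
  rx <- network@reactions
  lam <- lattice@spacing
  if (is.null(tau)) tau <- computeTimestep(lam, max(sp$D[sp$D > 0]))
  nSteps <- max(1L, round(duration / tau))
  if (is.null(recordInterval)) recordInterval <- duration
  recEvery <- max(1L, round(recordInterval / tau))
  nSteps <- ceiling(nSteps / recEvery) * recEvery

  d <- dim(lattice@sites)
  masks <- vapply(sp$allowed, .allowedMask, integer(1))
  bias <- network@bias[match(sp$name, network@bias$species), ]
  pool <- sp$pool

  ## reaction channels
  spIdx <- function(nm) match(nm, sp$name) - 1L
  reOrder <- ifelse(is.na(rx$r2), 1L, 2L)
  reR1 <- spIdx(rx$r1)
  reR2 <- ifelse(is.na(rx$r2), -1L, spIdx(rx$r2))
  reProducts <- lapply(rx$products, function(p) spIdx(.splitNames(p)))
  reMask <- vapply(rx$where, .allowedMask, integer(1))
  reRate <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    reRate[i] <- if (rx$units[i] == "M-1s-1")
      bimolecularStochasticRate(rx$rate[i], lam) else rx$rate[i]
    hasPool <- (!is.na(rx$r1[i]) && pool[match(rx$r1[i], sp$name)]) ||
      (!is.na(rx$r2[i]) && pool[match(rx$r2[i], sp$name)])
    if (hasPool && countScale != 1) {
      if (reOrder[i] < 2)
        stop("countScale requires pool species to react bimolecularly")
      reRate[i] <- reRate[i] / countScale
    }
  }

  ## trigger species: non-pool reactants
  reactants <- unique(c(rx$r1, rx$r2))
  trigger <- sp$name %in% reactants & !pool

  ## initial placement (deterministic per seed+replicate)
  typeSites <- lapply(siteTypeNames(), function(tn)
    which(lattice@sites == .SITE_TYPES[[tn]]))
  names(typeSites) <- siteTypeNames()
  vSite <- lam^3
  pos0 <- .withSeed(seed + 7919L * replicate, {
    lapply(seq_len(nrow(sp)), function(i) {
      if (is.na(sp$init_where[i]) || sp$init_value[i] <= 0)
        return(integer(0))
      if (identical(sp$init_where[i], "genes")) {
        gp <- lattice@genePositions
        if (nrow(gp) == 0) stop("network needs gene positions but the ",
                                "lattice has none")
        idx <- .linearIndex(gp, d)
        n <- round(sp$init_value[i])
        return(as.integer(idx[((seq_len(n) - 1L) %% length(idx)) + 1L]) - 1L)
      }
      region <- typeSites[[sp$init_where[i]]]
      if (length(region) == 0)
        stop("empty initial region '", sp$init_where[i], "' for species ",
             sp$name[i])
      n <- if (sp$init_mode[i] == "conc")
        concentrationToCount(sp$init_value[i], length(region) * vSite)
      else round(sp$init_value[i])
      if (pool[i]) n <- round(n * countScale)
      if (n == 0) return(integer(0))
      as.integer(sample(region, n, replace = TRUE)) - 1L
    })
  })

  trackIdx <- if (is.null(trackSpecies)) integer(0)
              else spIdx(trackSpecies)

  res <- rdme_core(
    sites = as.raw(lattice@sites), dims = as.integer(d),
    lambda = lam, tau = tau, n_steps = as.integer(nSteps),
    record_every = as.integer(recEvery),
    species_pos0 = pos0,
    D = sp$D, allowed_mask = as.integer(masks),
    Pn = bias$Pn, Ps = bias$Ps, trigger = trigger,
    re_order = as.integer(reOrder), re_r1 = as.integer(reR1),
    re_r2 = as.integer(reR2), re_products = reProducts,
    re_rate = reRate, re_sitemask = as.integer(reMask),
    bias_from = .SITE_TYPES[["nucleoplasm"]],
    bias_to = .SITE_TYPES[["speckle"]],
    seed = as.integer(seed), stream = as.integer(replicate),
    track_species = as.integer(trackIdx))

  counts <- array(res$counts,
                  dim = c(nrow(sp), 11L, length(res$times)))
  traj <- methods::new(
    "Trajectory",
    times = as.numeric(res$times), counts = counts,
    speciesNames = sp$name, compartmentNames = siteTypeNames(),
    tally = setNames(as.numeric(res$tally), rx$name),
    firstSeen = setNames(as.numeric(res$first_seen), sp$name),
    metadata = list(engine = "rdme", seed = seed, replicate = replicate,
                    tau = tau, lambda = lam, countScale = countScale,
                    variant = network@variant))
  if (length(trackIdx) > 0) {
    attr(traj, "track") <- res$track
    attr(traj, "trackSpecies") <- trackSpecies
    attr(traj, "dims") <- d
  }
  traj
}
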