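## Scripted reproductions of the compartmentalization, speckle-enhancement,
## speckle-anatomy and gene-distance experiments at reduced scale, plus the
## observables they report.

#' Coefficient of variation of replicate endpoints
#'
#' Sample standard deviation over sample mean. Undefined (NA with
#' attribute `undefined`) when the mean is zero, which happens when no
#' mRNA is produced.
#'
#' @param endpoints numeric vector of per-replicate endpoint counts
#'   (length >= 2).
#' @return numeric CV, or flagged NA.
#' @export
coefficientOfVariation <- function(endpoints) {
  if (length(endpoints) < 2) stop("need at least 2 replicates")
  m <- mean(endpoints)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  sd(endpoints) / m
}

#' Summarize replicate endpoints
#'
#' @param endpoints numeric vector.
#' @param condition list or one-row data.frame describing the condition.
#' @return one-row data.frame with n, mean, sd, cv (NA when mean is 0).
#' @export
replicateSummary <- function(endpoints, condition = list()) {
  cv <- coefficientOfVariation(endpoints)
  out <- data.frame(n = length(endpoints), mean = mean(endpoints),
                    sd = sd(endpoints), cv = as.numeric(cv))
  if (length(condition)) out <- cbind(as.data.frame(condition), out)
  out
}

#' Fraction of a species localized in speckles
#'
#' `N_speckle / (N_speckle + N_nucleoplasm)` at each recorded time; the
#' condition summary is the time average over the last half of the run.
#'
#' @param traj a [Trajectory-class] with speckle and nucleoplasm
#'   compartments.
#' @param species species name.
#' @return numeric vector over times, with the last-half time average in
#'   `attr(, "summary")` (NA, flagged, if the total is zero throughout).
#' @export
localizationFraction <- function(traj, species) {
  cn <- traj@compartmentNames
  spk <- if ("speckle" %in% cn) speciesCounts(traj, species, "speckle")
         else rep(0, length(traj@times))
  nuc <- speciesCounts(traj, species,
                       intersect(c("nucleoplasm", "nucleus"), cn))
  tot <- spk + nuc
  f <- ifelse(tot > 0, spk / tot, NA_real_)
  lastHalf <- f[traj@times >= max(traj@times) / 2]
  s <- if (all(is.na(lastHalf))) structure(NA_real_, undefined = TRUE)
       else mean(lastHalf, na.rm = TRUE)
  structure(f, summary = s)
}

#' Nucleus-only misassembly experiment
#'
#' Runs the nucleus-only assembly network (all particle-formation steps in
#' the nucleus plus the premature-binding misassembly channels) for 30 s
#' with the well-mixed engine and reports mean +- sd of misassembled and
#' correctly matured particle counts.
#'
#' @param nReps replicates (default 20).
#' @param duration seconds (default 30).
#' @param seed integer.
#' @param network a [misassemblyNetwork()].
#' @param nuclearVolume um^3.
#' @return list with `summary` (data.frame rows misassembled / mature) and
#'   the per-replicate endpoint matrix.
#' @export
runMisassemblyExperiment <- function(nReps = 20, duration = 30, seed = 1L,
                                     network = misassemblyNetwork(),
                                     nuclearVolume = 4 / 3 * pi * 4.2^3) {
  model <- misassemblyCompartmentModel(network, nuclearVolume)
  ep <- vapply(seq_len(nReps), function(r) {
    traj <- runSSA(model, duration, seed = seed, replicate = r)
    e <- endpointCounts(traj)
    c(mis = unname(e[["misassembled_U1"]] + e[["misassembled_U2"]]),
      mature = unname(e[["U1snRNP"]] + e[["U2snRNP"]]))
  }, numeric(2))
  list(summary = rbind(
         replicateSummary(ep["mis", ], list(outcome = "misassembled")),
         replicateSummary(ep["mature", ], list(outcome = "mature"))),
       endpoints = ep, seed = seed)
}

#' Pore-count / nuclear-size experiment
#'
#' Mature U1 and U2 counts after 30 s for a grid of pore-count scalings
#' and nuclear radii, using the well-mixed surrogate (pore transport as
#' diffusion-limited exchange, flux proportional to pore count) or the
#' reduced-lattice RDME.
#'
#' @param npcScale pore-count multipliers (default 0.8, 1.0, 1.2).
#' @param nuclearRadius radii in um (default 3.7, 4.7, 5.3).
#' @param nReps,duration,seed replication controls.
#' @param engine "ssa" (surrogate) or "rdme" (requires `latticeFactory`, a
#'   function(radius, npcScale, replicate) returning a built lattice).
#' @param latticeFactory see `engine`.
#' @param countScale pool count scaling for the RDME engine.
#' @return data.frame grid with per-condition mean/sd/cv of mature U1 and
#'   U2, plus the endpoint array in `attr(, "endpoints")`.
#' @export
runParticleFormationExperiment <- function(npcScale = c(0.8, 1, 1.2),
                                           nuclearRadius = c(3.7, 4.7, 5.3),
                                           nReps = 20, duration = 30,
                                           seed = 1L,
                                           engine = c("ssa", "rdme"),
                                           latticeFactory = NULL,
                                           countScale = 0.005) {
  engine <- match.arg(engine)
  net <- particleFormationNetwork()
  rows <- list()
  eps <- list()
  for (rn in nuclearRadius) {
    for (ns in npcScale) {
      ep <- if (engine == "ssa") {
        geom <- geometrySummary(config = geometryConfig(nuclearRadius = rn))
        model <- formationCompartmentModel(net, geom, npcScale = ns)
        vapply(seq_len(nReps), function(r) {
          traj <- runSSA(model, duration, seed = seed, replicate = r)
          e <- endpointCounts(traj)
          c(U1 = unname(e[["U1snRNP"]]), U2 = unname(e[["U2snRNP"]]))
        }, numeric(2))
      } else {
        vapply(seq_len(nReps), function(r) {
          lat <- latticeFactory(rn, ns, r)
          traj <- runRDME(lat, net, duration, seed = seed, replicate = r,
                          countScale = countScale)
          e <- endpointCounts(traj)
          c(U1 = unname(e[["U1snRNP"]]), U2 = unname(e[["U2snRNP"]]))
        }, numeric(2))
      }
      key <- sprintf("r%.1f_s%.1f", rn, ns)
      eps[[key]] <- ep
      rows[[key]] <- cbind(
        data.frame(nuclearRadius = rn, npcScale = ns),
        U1_mean = mean(ep["U1", ]), U1_sd = sd(ep["U1", ]),
        U2_mean = mean(ep["U2", ]), U2_sd = sd(ep["U2", ]),
        n = nReps)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "endpoints") <- eps
  out
}

#' Speckle localization sweep (splicing enhancement and noise)
#'
#' Runs the co-transcriptional splicing system for `duration` seconds at
#' each target localization (0 = no-speckle control) and particle
#' concentration, and reports spliced mRNA, free transcripts, CV and the
#' fold-enhancement relative to the control.
#'
#' @param localizations target speckle fractions (0 for the control).
#' @param particleConc molar concentrations to sweep (default 1 nM).
#' @param nGenes,duration,nReps,seed controls (defaults 20 genes, 900 s,
#'   20 replicates).
#' @param geom a [geometrySummary()].
#' @return data.frame with one row per condition; per-replicate mRNA
#'   endpoints in `attr(, "endpoints")`.
#' @export
runSpeckleSweep <- function(localizations = c(0, 0.1, 0.25, 0.4, 0.57,
                                              0.7, 0.85),
                            particleConc = 1e-9, nGenes = 20,
                            duration = 900, nReps = 20, seed = 1L,
                            geom = geometrySummary()) {
  rows <- list()
  eps <- list()
  for (conc in particleConc) {
    ctrl <- NULL
    for (loc in localizations) {
      ep <- vapply(seq_len(nReps), function(r) {
        res <- runCotxSplicing(nGenes = nGenes, particleConc = conc,
                               localization = loc, geom = geom,
                               duration = duration,
                               recordInterval = duration,
                               seed = seed, replicate = r)
        c(mRNA = res$mRNA, free = res$freeTranscripts)
      }, numeric(2))
      key <- sprintf("c%g_l%g", conc, loc)
      eps[[key]] <- ep
      if (loc == 0) ctrl <- mean(ep["mRNA", ])
      rows[[key]] <- data.frame(
        particleConc = conc, localization = loc, n = nReps,
        mRNA_mean = mean(ep["mRNA", ]), mRNA_sd = sd(ep["mRNA", ]),
        mRNA_cv = as.numeric(coefficientOfVariation(ep["mRNA", ])),
        free_mean = mean(ep["free", ]), free_sd = sd(ep["free", ]),
        fold = if (!is.null(ctrl) && ctrl > 0)
          mean(ep["mRNA", ]) / ctrl else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "endpoints") <- eps
  out
}

#' Speckle number/size sweep at constant total speckle volume
#'
#' Splits `totalFraction` of the nuclear volume over `n` speckles (radius
#' shrinking as n^(-1/3), total surface area growing as n^(1/3)) and
#' measures mRNA production with the nucleus-scale RDME.
#'
#' @param nSpeckles vector of speckle counts.
#' @param totalFraction total speckle volume fraction of the nucleus
#'   (default 0.10).
#' @param duration,nReps,seed controls.
#' @param spacing lattice spacing for the nucleus-only build (um).
#' @param particleConc molar U1/U2/triU concentration.
#' @return data.frame per condition: speckle diameter, total surface area,
#'   mRNA mean/sd.
#' @export
runSpeckleAnatomySweep <- function(nSpeckles = c(5, 20, 50, 80),
                                   totalFraction = 0.10,
                                   duration = 900, nReps = 20, seed = 1L,
                                   spacing = 0.128, particleConc = 1e-9) {
  rows <- list()
  for (n in nSpeckles) {
    cfg <- geometryConfig(spacing = spacing, nucleusOnly = TRUE,
                          nSpeckles = n, speckleTotalFraction = totalFraction,
                          nGenes = 20, seed = seed)
    ep <- vapply(seq_len(nReps), function(r) {
      lat <- .rebuildNuclearBodies(cfg, seed + r)
      geomL <- geometrySummary(lat)
      net <- splicingNetwork(nGenes = 20, particleConc = particleConc,
                             localization = 0.57,
                             speckleVolume = geomL$speckleVolume,
                             nucleoplasmVolume = geomL$nucleusVolume)
      traj <- runRDME(lat, net, duration, seed = seed, replicate = r)
      e <- endpointCounts(traj)
      unname(e[["mRNA_nuc"]] + e[["mRNA_cyt"]])
    }, numeric(1))
    rn <- cfg$nuclearRadius
    rs <- (3 * totalFraction * .sphereVol(rn) / (4 * pi * n))^(1 / 3)
    rows[[as.character(n)]] <- data.frame(
      nSpeckles = n, diameter = 2 * rs, surfaceArea = n * 4 * pi * rs^2,
      mRNA_mean = mean(ep), mRNA_sd = sd(ep), n = nReps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-distance sweep
#'
#' Places the 20 active genes at distance `d` from the speckle surfaces on
#' a nucleus-scale lattice, runs the splicing network with mRNA export
#' through the pores, and reports cytoplasmic mRNA versus distance
#' (organelle placement re-randomized every replicate).
#'
#' @param distances gene distances in um.
#' @param duration,nReps,seed controls.
#' @param spacing lattice spacing (um).
#' @param localization particle localization in speckles (default the
#'   experimentally anchored 0.57).
#' @param particleConc molar concentration (default 1 nM).
#' @return data.frame per distance with cytoplasmic and total mRNA;
#'   endpoint vectors in `attr(, "endpoints")`.
#' @export
runGeneDistanceSweep <- function(distances = c(0.05, 0.1, 0.2, 0.4),
                                 duration = 900, nReps = 20, seed = 1L,
                                 spacing = 0.128, localization = 0.57,
                                 particleConc = 1e-9) {
  rows <- list()
  eps <- list()
  for (d in distances) {
    cfg <- geometryConfig(spacing = spacing, nucleusOnly = TRUE,
                          nGenes = 20, geneDistance = d, seed = seed)
    ep <- vapply(seq_len(nReps), function(r) {
      lat <- .rebuildNuclearBodies(cfg, seed + r)
      geomL <- geometrySummary(lat)
      net <- splicingNetwork(nGenes = 20, particleConc = particleConc,
                             localization = localization,
                             speckleVolume = geomL$speckleVolume,
                             nucleoplasmVolume = geomL$nucleusVolume)
      traj <- runRDME(lat, net, duration, seed = seed, replicate = r)
      e <- endpointCounts(traj)
      c(cyt = unname(e[["mRNA_cyt"]]),
        tot = unname(e[["mRNA_nuc"]] + e[["mRNA_cyt"]]))
    }, numeric(2))
    key <- sprintf("d%.3f", d)
    eps[[key]] <- ep
    rows[[key]] <- data.frame(
      distance = d, n = nReps,
      mRNAcyt_mean = mean(ep["cyt", ]), mRNAcyt_sd = sd(ep["cyt", ]),
      mRNAtot_mean = mean(ep["tot", ]), mRNAtot_sd = sd(ep["tot", ]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "endpoints") <- eps
  out
}

## Rebuild only the stochastic nuclear content (speckles, Cajal bodies,
## genes, pores) on a cached nuclear shell, so per-replicate geometry
## randomization stays cheap.
.rebuildNuclearBodies <- local({
  cache <- new.env(parent = emptyenv())
  function(cfg, seed) {
    key <- sprintf("%g_%g_%g", cfg$spacing, cfg$nuclearRadius, cfg$edge)
    base <- cache[[key]]
    if (is.null(base)) {
      baseCfg <- cfg
      baseCfg$nSpeckles <- 0L
      baseCfg$nCajal <- 0L
      baseCfg$nGenes <- 0L
      base <- buildCell(baseCfg)
      cache[[key]] <- base
    }
    lat <- base
    lat@config <- unclass(cfg)
    lat@config$npcCount <- base@config$npcCount
    lat@seed <- as.integer(seed)
    if (cfg$nCajal > 0)
      lat <- placeCajal(lat, cfg$nCajal, cfg$cajalRadius, seed = seed + 31L)
    if (cfg$nSpeckles > 0) {
      lat <- placeSpeckles(lat, cfg$nSpeckles, cfg$speckleRadius,
                           cfg$speckleTotalFraction, seed = seed + 41L)
      lat@config$speckleRadiusRealized <- attr(lat, "radius")
    }
    if (cfg$nGenes > 0)
      lat <- placeGenes(lat, cfg$nGenes, cfg$geneDistance,
                        cfg$geneShellWidth, seed = seed + 61L)
    lat
  }
})

#' Cytoplasmic-crowding (organelle removal) experiment
#'
#' Runs the particle-formation network on the reduced-resolution whole-cell
#' lattice with and without cytoplasmic organelles (ER, mitochondria,
#' Golgi), organelle placement re-randomized per replicate, and reports the
#' percent change in mature U1 production at 30 s.
#'
#' @param nReps replicates per arm (default 20).
#' @param duration seconds (default 30).
#' @param seed integer.
#' @param spacing lattice spacing (um; default 0.256).
#' @param countScale protein-pool count scaling (default 0.005).
#' @return list with `percentIncrease`, per-arm summaries, and endpoints.
#' @export
runOrganelleRemovalExperiment <- function(nReps = 20, duration = 30,
                                          seed = 1L, spacing = 0.256,
                                          countScale = 0.005) {
  net <- particleFormationNetwork()
  arm <- function(withOrganelles) {
    vapply(seq_len(nReps), function(r) {
      cfg <- geometryConfig(spacing = spacing, nGenes = 0,
                            cytoplasmicOrganelles = withOrganelles,
                            seed = seed * 1000L + r)
      lat <- suppressWarnings(buildCell(cfg))
      traj <- runRDME(lat, net, duration, seed = seed, replicate = r,
                      countScale = countScale)
      e <- endpointCounts(traj)
      unname(e[["U1snRNP"]])
    }, numeric(1))
  }
  full <- arm(TRUE)
  empty <- arm(FALSE)
  list(percentIncrease = 100 * (mean(empty) - mean(full)) / mean(full),
       summary = rbind(
         replicateSummary(full, list(arm = "with_organelles")),
         replicateSummary(empty, list(arm = "without_organelles"))),
       endpoints = list(with_organelles = full, without_organelles = empty))
}

#' First-assembly dissection
#'
#' From a particle-formation trajectory, the times at which the first
#' nuclear U1 snRNA transcript, the first completed cytoplasmic
#' U1snRNA.Sm7, and the first mature U1 particle appeared; stage durations
#' and which stage took longest. Stages never reached are flagged
#' censored.
#'
#' @param traj a formation-network [Trajectory-class].
#' @return data.frame with stage, time, duration, censored.
#' @export
firstEventDissection <- function(traj) {
  fs <- traj@firstSeen
  t1 <- fs[["U1snRNA_nuc"]]
  t2 <- fs[["U1snRNA_Sm7"]]
  t3 <- fs[["U1snRNP"]]
  cen <- c(t1 < 0, t2 < 0, t3 < 0)
  times <- c(t1, t2, t3)
  times[cen] <- NA
  durations <- c(times[1],
                 times[2] - times[1],
                 times[3] - times[2])
  out <- data.frame(
    stage = c("nuclear_transcription", "cytoplasmic_assembly",
              "nuclear_maturation"),
    firstTime = times, duration = durations,
    censored = cen | is.na(durations))
  attr(out, "longest") <- if (all(!out$censored))
    out$stage[which.max(out$duration)] else NA_character_
  out
}
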