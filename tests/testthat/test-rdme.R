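# Property tests of the lattice engine: conservation, the Einstein
# relation, the speckle partition closed form, and agreement with the
# exact well-mixed sampler in the single-subvolume limit.

.freeSpecies <- function(n = 500, D = 1) {
  spRow("W", D, "nucleoplasm,speckle", init_mode = "count",
        init_value = n, init_where = "nucleoplasm")
}

test_that("diffusion conserves every species exactly", {
  lat <- smallCell()
  net <- particleFormationNetwork()
  net@reactions <- net@reactions[0, ]  # diffusion only
  traj <- runRDME(lat, net, duration = 0.05, recordInterval = 0.01,
                  seed = 3, countScale = 0.02)
  totals <- apply(traj@counts, c(1, 3), sum)
  for (i in seq_len(nrow(totals)))
    expect_true(all(totals[i, ] == totals[i, 1]))
})

test_that("mean squared displacement follows 6 D t", {
  lat <- uniformBox(96, 0.1)  # large arena: boundary effects negligible
  D <- 1
  net <- adhocNetwork(.freeSpecies(2000, D),
                      rxRow("noop", "W", NA, "W", 0, "s-1", "nucleoplasm"))
  tau <- computeTimestep(0.1, D)
  traj <- runRDME(lat, net, duration = 40 * tau, tau = tau,
                  recordInterval = 4 * tau, seed = 9, trackSpecies = "W")
  track <- attr(traj, "track")
  d <- attr(traj, "dims")
  coords <- function(idx) (arrayInd(idx + 1L, d) - 0.5) * 0.1
  p0 <- coords(track[[1]][[1]])
  msd <- vapply(seq_along(track), function(i) {
    mean(rowSums((coords(track[[i]][[1]]) - p0)^2))
  }, numeric(1))
  t <- timePoints(traj)
  fit <- sum(msd * 6 * D * t) / sum((6 * D * t)^2)  # slope vs theory ~1
  expect_lt(abs(fit - 1), 0.05)
})

test_that("speckle occupancy reaches the detailed-balance partition", {
  # nucleoplasm box with a central spherical speckle
  lat <- uniformBox(20, 0.1)
  ctr <- rep(1.0, 3)
  lat <- stencilPrimitive(lat, shpSphere(ctr, 0.35), "speckle")
  nS <- sum(lat@sites == SpliceCell:::.SITE_TYPES[["speckle"]])
  nN <- sum(lat@sites == SpliceCell:::.SITE_TYPES[["nucleoplasm"]])
  for (rho in c(1, 3, 10, 100)) {
    sp <- .freeSpecies(400, D = 1)
    net <- adhocNetwork(sp, rxRow("noop", "W", NA, "W", 0, "s-1",
                                  "nucleoplasm"),
                        bias = data.frame(species = "W", Pn = 1,
                                          Ps = 1 / rho))
    fExp <- rho * nS / (rho * nS + nN)
    nRep <- 4
    f <- vapply(seq_len(nRep), function(r) {
      traj <- runRDME(lat, net, duration = 12, recordInterval = 1,
                      seed = 40 + rho, replicate = r)
      w <- speciesCounts(traj, "W", "speckle")
      late <- w[timePoints(traj) >= 6]
      mean(late) / 400
    }, numeric(1))
    se <- max(sd(f) / sqrt(nRep), 0.004)
    expect_lt(abs(mean(f) - fExp), 3 * se)
  }
})

test_that("single-subvolume RDME reproduces the exact SSA distribution", {
  lat <- uniformBox(2, 0.1)  # 8 sites, one site type
  n0 <- 20
  mkSp <- function() rbind(
    spRow("A", 1, "nucleoplasm", init_mode = "count", init_value = n0,
          init_where = "nucleoplasm"),
    spRow("B", 1, "nucleoplasm", init_mode = "count", init_value = n0,
          init_where = "nucleoplasm"),
    spRow("C", 1, "nucleoplasm"))
  rx <- rbind(
    rxRow("bind", "A", "B", "C", 1.02e8, "M-1s-1", "nucleoplasm"),
    rxRow("unbind", "C", NA, c("A", "B"), 3.05, "s-1", "nucleoplasm"))
  net <- adhocNetwork(mkSp(), rx)
  n <- 200
  rdme <- vapply(seq_len(n), function(r)
    endpointCounts(runRDME(lat, net, duration = 1, seed = 31,
                           replicate = r))[["C"]], numeric(1))
  cmp <- data.frame(name = "box", volume = 8 * 0.1^3,
                    site_types = "nucleoplasm")
  model <- compartmentModel(cmp, NULL, net)
  ssa <- vapply(seq_len(n), function(r)
    endpointCounts(runSSA(model, 1, seed = 32, replicate = r))[["C"]],
    numeric(1))
  expect_gt(suppressWarnings(ks.test(rdme, ssa))$p.value, 0.01)
})

test_that("first-order decay matches the exponential mean and tau-halving is stable", {
  lat <- uniformBox(6, 0.1)
  mkNet <- function() {
    sp <- rbind(
      spRow("A", 1, "nucleoplasm", init_mode = "count", init_value = 200,
            init_where = "nucleoplasm"),
      spRow("B", 1, "nucleoplasm"))
    adhocNetwork(sp, rxRow("decay", "A", NA, "B", 0.5, "s-1", "nucleoplasm"))
  }
  run <- function(tauScale, reps, seedBase) {
    tau <- computeTimestep(0.1, 1) * tauScale
    vapply(seq_len(reps), function(r)
      endpointCounts(runRDME(lat, mkNet(), duration = 2, tau = tau,
                             seed = seedBase, replicate = r))[["A"]],
      numeric(1))
  }
  a1 <- run(1, 150, 51)
  mu <- 200 * exp(-0.5 * 2)
  se <- sqrt(200 * exp(-1) * (1 - exp(-1))) / sqrt(150)  # binomial survival
  expect_lt(abs(mean(a1) - mu), 3 * se)

  a2 <- run(0.5, 150, 52)
  seDiff <- sqrt(var(a1) / 150 + var(a2) / 150)
  expect_lt(abs(mean(a1) - mean(a2)), 3 * seDiff)
})

test_that("pore transport requires pore sites and engines stay deterministic", {
  # lattice without pores: no export events over any run
  cfg <- geometryConfig(spacing = 0.256, npcDensity = 0, nGenes = 0,
                        nSpeckles = 0, nCajal = 0, erFraction = 0,
                        golgiSheets = 0, nMito = 0)
  lat <- suppressWarnings(buildCell(cfg))
  net <- particleFormationNetwork()
  traj <- runRDME(lat, net, duration = 0.5, seed = 6, countScale = 0.002)
  expect_identical(unname(traj@tally[["export_U1"]] +
                            traj@tally[["export_U2"]]), 0)

  # identical (seed, replicate) => identical trajectories
  lat2 <- smallCell()
  t1 <- runRDME(lat2, net, duration = 0.2, seed = 8, replicate = 3,
                countScale = 0.02)
  t2 <- runRDME(lat2, net, duration = 0.2, seed = 8, replicate = 3,
                countScale = 0.02)
  expect_identical(t1@counts, t2@counts)
  t3 <- runRDME(lat2, net, duration = 0.2, seed = 8, replicate = 4,
                countScale = 0.02)
  expect_false(identical(t3@counts, t1@counts))

  # duration ~ 0: trajectory reduces to the initial state
  t0 <- runRDME(lat2, net, duration = 1e-9, seed = 8, countScale = 0.02)
  expect_true(all(t0@counts[, , 1] == t0@counts[, , dim(t0@counts)[3]]))
})

test_that("early export flux scales with the pore-site count", {
  mk <- function(dens) {
    cfg <- geometryConfig(spacing = 0.128, nucleusOnly = TRUE,
                          npcDensity = dens, nSpeckles = 0, nCajal = 0,
                          nGenes = 0, seed = 2)
    suppressWarnings(buildCell(cfg))
  }
  lat1 <- mk(3.5); lat2 <- mk(7)
  siteRatio <- sum(lat2@sites == SpliceCell:::.SITE_TYPES[["npc"]]) /
    sum(lat1@sites == SpliceCell:::.SITE_TYPES[["npc"]])
  net <- particleFormationNetwork()
  # preload nuclear snRNA so flux is measurable immediately
  net@species$init_value[net@species$name == "U1snRNA_nuc"] <- 400
  net@species$init_where[net@species$name == "U1snRNA_nuc"] <- "nucleoplasm"
  flux <- function(lat, reps, seedBase) vapply(seq_len(reps), function(r) {
    traj <- runRDME(lat, net, duration = 0.1, seed = seedBase,
                    replicate = r, countScale = 0.02)
    unname(traj@tally[["export_U1"]])
  }, numeric(1))
  f1 <- flux(lat1, 12, 61)
  f2 <- flux(lat2, 12, 62)
  ratio <- mean(f2) / mean(f1)
  se <- ratio * sqrt(var(f2) / (12 * mean(f2)^2) +
                       var(f1) / (12 * mean(f1)^2))
  expect_gt(ratio, 1.3)  # more pores, more flux
  expect_lt(abs(ratio - siteRatio), 3 * se + 0.25 * siteRatio)
})
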