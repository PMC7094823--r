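test_that("coefficient of variation and replicate summaries", {
  expect_equal(coefficientOfVariation(c(2, 4, 6)), 0.5)
  expect_identical(coefficientOfVariation(c(3, 3, 3)), 0)
  cv0 <- coefficientOfVariation(c(0, 0, 0))
  expect_true(is.na(cv0))
  expect_true(isTRUE(attr(cv0, "undefined")))
  expect_error(coefficientOfVariation(5), "at least 2")

  s <- replicateSummary(c(2, 4, 6), list(condition = "x"))
  expect_identical(s$n, 3L)
  expect_equal(s$cv, 0.5)
})

test_that("localization fraction handles absent speckles and biased runs", {
  # trajectory with all mass in the nucleoplasm: fraction 0
  counts <- array(0, dim = c(1, 2, 3))
  counts[1, 1, ] <- 10
  traj <- methods::new("Trajectory", times = c(0, 1, 2), counts = counts,
                       speciesNames = "U1",
                       compartmentNames = c("nucleoplasm", "speckle"),
                       tally = numeric(0), firstSeen = numeric(0),
                       metadata = list())
  f <- localizationFraction(traj, "U1")
  expect_true(all(f == 0))
  expect_equal(attr(f, "summary"), 0)

  # zero total is flagged undefined
  counts0 <- array(0, dim = c(1, 2, 2))
  traj0 <- methods::new("Trajectory", times = c(0, 1), counts = counts0,
                        speciesNames = "U1",
                        compartmentNames = c("nucleoplasm", "speckle"),
                        tally = numeric(0), firstSeen = numeric(0),
                        metadata = list())
  f0 <- localizationFraction(traj0, "U1")
  expect_true(isTRUE(attr(attr(f0, "summary"), "undefined")))
})

test_that("exchange-tuned localization hits its target in the splicing surrogate", {
  g <- geometrySummary()
  target <- 0.10
  nRep <- 10
  f <- vapply(seq_len(nRep), function(r) {
    res <- runCotxSplicing(localization = target, geom = g, duration = 600,
                           seed = 9, replicate = r)
    sum(res$U1[2], res$U2[2], res$triU[2]) /
      sum(res$U1, res$U2, res$triU)
  }, numeric(1))
  expect_lt(abs(mean(f) - target), 0.02)
})

test_that("misassembly experiment is reproducible and responds to its knobs", {
  a <- runMisassemblyExperiment(nReps = 4, seed = 21)
  b <- runMisassemblyExperiment(nReps = 4, seed = 21)
  expect_identical(a$endpoints, b$endpoints)

  off <- runMisassemblyExperiment(nReps = 3, seed = 5,
                                  network = misassemblyNetwork(misRate = 0))
  expect_identical(unname(off$endpoints["mis", ]), c(0, 0, 0))
  expect_gt(mean(off$endpoints["mature", ]), 0)
})

test_that("pore-count surrogate shows the production trend across the grid", {
  grid <- runParticleFormationExperiment(npcScale = c(0.8, 1.2),
                                         nuclearRadius = c(4.2),
                                         nReps = 10, seed = 31)
  eps <- attr(grid, "endpoints")
  lo <- eps[["r4.2_s0.8"]]["U1", ]
  hi <- eps[["r4.2_s1.2"]]["U1", ]
  tt <- t.test(hi, lo, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
  # U2 moves the same way
  expect_gt(mean(eps[["r4.2_s1.2"]]["U2", ]),
            mean(eps[["r4.2_s0.8"]]["U2", ]))
})

test_that("starved splicing produces no mRNA and flags the noise measure", {
  res <- runSpeckleSweep(localizations = c(0, 0.1), particleConc = 1e-10,
                         nReps = 4, duration = 600, seed = 17)
  expect_identical(res$mRNA_mean, c(0, 0))
  expect_true(all(is.na(res$mRNA_cv)))
})

test_that("first-assembly dissection orders stages causally", {
  model <- formationCompartmentModel()
  traj <- runSSA(model, 30, seed = 41)
  dis <- firstEventDissection(traj)
  expect_identical(dis$stage[1], "nuclear_transcription")
  expect_false(any(dis$censored))
  # causal ordering of first-appearance times
  expect_true(all(diff(dis$firstTime) > 0))

  # all-zero rates: everything censored
  net0 <- particleFormationNetwork(params = list(ktrans1 = 0, ktrans2 = 0))
  traj0 <- runSSA(formationCompartmentModel(net0), 5, seed = 2)
  dis0 <- firstEventDissection(traj0)
  expect_true(all(dis0$censored))
  expect_true(is.na(attr(dis0, "longest")))
})

test_that("production is bounded by the transcription budget", {
  model <- formationCompartmentModel()
  traj <- runSSA(model, 30, seed = 43)
  e <- endpointCounts(traj)
  budget <- 30 * (0.285 + 0.224) * 30  # genes x rates x duration
  made <- sum(traj@tally[grepl("transcription", names(traj@tally))])
  expect_lte(e[["U1snRNP"]] + e[["U2snRNP"]], made)
  expect_lt(made, budget * 1.5)
})
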