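test_that("particle-formation network expands to the canonical 20 reactions", {
  net <- particleFormationNetwork()
  rx <- reactionTable(net)
  expect_identical(nrow(rx), 20L)

  # every published rate constant, by channel
  rates <- setNames(rx$rate, rx$name)
  expect_identical(unname(rates[c("transcription_U1", "transcription_U2")]),
                   c(0.285, 0.224))
  expect_identical(unname(rates[c("export_U1", "import_U1")]), c(2e4, 2e4))
  expect_identical(unname(rates[c("bindG5_U1", "unbindG5_U1")]),
                   c(1.02e8, 3.05))
  expect_identical(unname(rates[c("rnpExchange_U1", "rnpExchange_U2")]),
                   c(5.9e7, 1.18e7))
  expect_identical(unname(rates[c("bindSm2_U1", "unbindSm2_U1")]),
                   c(1.39e8, 2.78))
  expect_identical(unname(rates[c("mature_U1", "unmature_U1")]),
                   c(1.22e7, 4.8e-4))
  expect_identical(unname(rates[c("mature_U2", "unmature_U2")]),
                   c(0.24e7, 4.8e-4))

  # unit discipline: all association constants declared bimolecular,
  # everything else first order
  bim <- rx$units == "M-1s-1"
  expect_identical(sort(rx$name[bim]),
                   sort(c("bindG5_U1", "bindG5_U2", "rnpExchange_U1",
                          "rnpExchange_U2", "bindSm2_U1", "bindSm2_U2",
                          "mature_U1", "mature_U2")))
  expect_true(all(is.na(rx$r2[!bim])))
  expect_true(validObject(net))
})

test_that("blocked pore transport yields no cytoplasmic or mature species", {
  net <- particleFormationNetwork(params = list(knpc = 0))
  geom <- geometrySummary(config = geometryConfig())
  geom$poreArea <- 0
  model <- formationCompartmentModel(net, geom)
  traj <- runSSA(model, duration = 10, seed = 4)
  e <- endpointCounts(traj)
  expect_identical(unname(e[["U1snRNA_cyt"]]), 0)
  expect_identical(unname(e[["U1snRNP"]]), 0)
  expect_gt(e[["U1snRNA_nuc"]], 0)  # transcription still runs
})

test_that("misassembly variant is nucleus-only with terminal error channels", {
  net <- misassemblyNetwork()
  sp <- speciesTable(net)
  rx <- reactionTable(net)
  expect_true(all(c("misassembled_U1", "misassembled_U2") %in% sp$name))
  # no reaction fires in the cytoplasm and nothing is ever a product of the
  # misassembled species (terminal)
  expect_false(any(grepl("cytoplasm", rx$where)))
  expect_false(any(grepl("misassembled", rx$r1)))

  # zero-rate misassembly reduces to nucleus-only correct assembly
  net0 <- misassemblyNetwork(misRate = 0)
  model <- misassemblyCompartmentModel(net0)
  traj <- runSSA(model, duration = 10, seed = 2)
  e <- endpointCounts(traj)
  expect_identical(unname(e[["misassembled_U1"]] + e[["misassembled_U2"]]), 0)
  expect_gt(e[["U1snRNP"]], 0)
})

test_that("splicing network carries the Table rates and the 28 Kb gene", {
  net <- splicingNetwork()
  rx <- reactionTable(net)
  rates <- setNames(rx$rate, rx$name)
  expect_identical(unname(rates[c("transcription", "bindU1", "unbindU1")]),
                   c(4.7e-3, 4.66e7, 1.57))
  expect_identical(unname(rates[c("bindU2", "unbindU2")]), c(8.8e7, 0.062))
  expect_identical(unname(rates[c("bindTriU", "unbindTriU", "splice")]),
                   c(4.66e7, 1.55, 0.067))
  # activation is first order: the printed constant over N_A lambda^3
  expect_equal(unname(rates[["activate"]]),
               bimolecularStochasticRate(6e4, 0.064), tolerance = 1e-12)
  expect_equal(unname(rates[["activate"]]), 0.38, tolerance = 1e-2)

  expect_equal(geneLengthBases(), 8 * 3400 + 9 * 137)  # 28,433 b
  expect_equal(geneLengthBases() / 1e3, 28, tolerance = 0.02)

  # kspl = 0: no mRNA ever, complexes accumulate
  res <- runCotxSplicing(nGenes = 20, particleConc = 5e-9,
                         localization = 0, duration = 600, seed = 5,
                         params = list(kspl = 0))
  expect_identical(res$mRNA, 0)
  expect_gt(res$boundIntrons, 0)
})

test_that("network definitions round-trip through the text format", {
  net <- misassemblyNetwork()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeNetwork(net, f)
  back <- readNetwork(f)
  expect_equal(back@species, net@species)
  expect_equal(back@reactions, net@reactions)
  expect_equal(back@bias, net@bias)
  expect_identical(back@variant, net@variant)
  expect_error(readNetwork(withr::local_tempfile(lines = "foo: 1",
                                                 fileext = ".yaml")),
               "not a SpliceCell network")
})

test_that("localization bias inverts the partition formula", {
  # rho for 10% occupancy with V_s = 0.01 V_n is 100/9 = 11.1
  b <- biasForLocalization(0.10, speckleVolume = 1, nucleoplasmVolume = 100)
  expect_equal(b[["Pn"]] / b[["Ps"]], 100 / 9, tolerance = 1e-12)
  expect_identical(b[["Pn"]], 1)
  # equal volumes, target 0.5: no bias
  b2 <- biasForLocalization(0.5, 1, 1)
  expect_equal(b2[["Pn"]] / b2[["Ps"]], 1)
  expect_error(biasForLocalization(0, 1, 1), "in \\(0, 1\\)")
})
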