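test_that("voxelized spheres converge to analytic volumes and respect painter order", {
  lat <- SpliceCell:::.emptyLattice(3.2, 0.1)
  ctr <- rep(1.6, 3)
  # r = 12 lambda: voxel volume within 1% of analytic
  lat2 <- stencilPrimitive(lat, shpSphere(ctr, 1.2), "cytoplasm")
  vox <- attr(lat2, "painted") * 0.1^3
  expect_lt(abs(vox / (4 / 3 * pi * 1.2^3) - 1), 0.01)

  # r = 0 paints nothing
  lat0 <- stencilPrimitive(lat, shpSphere(ctr, 0), "cytoplasm")
  expect_identical(attr(lat0, "painted"), 0L)

  # later paints win on overlap
  latp <- stencilPrimitive(lat, shpSphere(c(1.4, 1.6, 1.6), 0.5), "nucleoplasm")
  latp <- stencilPrimitive(latp, shpSphere(c(1.8, 1.6, 1.6), 0.5), "speckle")
  overlap <- latp@sites[16, 16, 16]  # center of box, inside both
  expect_identical(overlap, SpliceCell:::.SITE_TYPES[["speckle"]])

  expect_error(shpSphere(ctr, -1), "invalid shape")
  expect_error(shpSpherocylinder(ctr, ctr + 1, 0), "invalid shape")
})

test_that("membranes are topologically closed shells", {
  lat <- SpliceCell:::.emptyLattice(6.4, 0.1)
  lat <- buildMembranes(lat, cellRadius = 2.9, nuclearRadius = 1.4,
                        thickness = 0.2)
  expect_identical(adjacencyCount(lat, "cytoplasm", "extracellular"), 0L)
  expect_identical(adjacencyCount(lat, "nucleoplasm", "cytoplasm"), 0L)

  # a one-spacing shell on a large sphere is still closed
  lat1 <- SpliceCell:::.emptyLattice(6.4, 0.1)
  lat1 <- buildMembranes(lat1, cellRadius = 2.9, nuclearRadius = 1.4,
                         thickness = 0.1)
  expect_identical(adjacencyCount(lat1, "cytoplasm", "extracellular"), 0L)
  expect_identical(adjacencyCount(lat1, "nucleoplasm", "cytoplasm"), 0L)

  # thinner than the lattice spacing would leak
  expect_error(buildMembranes(lat, 2.9, 1.4, 0.05), "leak")

  # shell volume sanity: voxel count within 10% of the analytic shell
  nShell <- sum(lat@sites == SpliceCell:::.SITE_TYPES[["nuclear_membrane"]])
  vExact <- 4 / 3 * pi * (1.6^3 - 1.4^3)
  expect_lt(abs(nShell * 0.1^3 / vExact - 1), 0.1)
})

test_that("NPC count follows density x area and channels connect the compartments", {
  cfg <- geometryConfig(spacing = 0.128, nucleusOnly = TRUE, nSpeckles = 0,
                        nCajal = 0, nGenes = 0, seed = 1)
  lat <- suppressWarnings(buildCell(cfg))
  expect_identical(lat@config$npcCount, as.integer(round(7 * 4 * pi * 4.2^2)))  # 1552
  # the formula count is within 5% of the printed lattice realization (1515)
  expect_lt(abs(lat@config$npcCount / 1515 - 1), 0.05)

  # density scaling: counts scale 1.2 : 0.8 within rounding
  n12 <- round(7 * 1.2 * 4 * pi * 4.2^2)
  n08 <- round(7 * 0.8 * 4 * pi * 4.2^2)
  expect_equal(n12 / n08, 1.2 / 0.8, tolerance = 1e-3)

  # every npc site set touches both nucleoplasm and cytoplasm somewhere,
  # and no nucleoplasm-cytoplasm contact bypasses the membrane/pores
  expect_gt(adjacencyCount(lat, "npc", "nucleoplasm"), 0L)
  expect_gt(adjacencyCount(lat, "npc", "cytoplasm"), 0L)
  expect_identical(adjacencyCount(lat, "nucleoplasm", "cytoplasm"), 0L)

  # zero density: impermeable membrane
  cfg0 <- geometryConfig(spacing = 0.128, nucleusOnly = TRUE, npcDensity = 0,
                         nSpeckles = 0, nCajal = 0, nGenes = 0)
  lat0 <- buildCell(cfg0)
  expect_identical(lat0@config$npcCount, 0L)
  expect_identical(sum(lat0@sites == SpliceCell:::.SITE_TYPES[["npc"]]), 0L)
  expect_error(placeNPCs(lat0, density = -1), ">= 0")
})

test_that("ER growth hits its target fraction deterministically", {
  base <- suppressWarnings(buildCell(smallCellConfig(erFraction = 0)))
  er1 <- growER(base, 0.045, seed = 9)
  expect_equal(volumeFraction(er1, "er"), 0.045, tolerance = 0.002)

  # bit-identical under the same seed; different site sets otherwise
  er2 <- growER(base, 0.045, seed = 9)
  expect_identical(er1@sites, er2@sites)
  er3 <- growER(base, 0.045, seed = 10)
  expect_false(identical(er1@sites, er3@sites))
  expect_equal(volumeFraction(er3, "er"), volumeFraction(er1, "er"),
               tolerance = 0.002)

  # target 0: no ER; unreachable target errors with the achievable maximum
  expect_identical(growER(base, 0)@sites, base@sites)
  expect_error(growER(base, 0.99, seed = 1), "unreachable")
})

test_that("mitochondria fill the expected volume in both morphologies", {
  cfg <- geometryConfig(spacing = 0.128, nGenes = 0, nSpeckles = 0, nCajal = 0,
                        erFraction = 0, golgiSheets = 0, nMito = 400, seed = 3)
  lat <- suppressWarnings(buildCell(cfg))
  # 400 spherocylinders x 0.144 um^3 over the 3000 um^3 cell, voxelized
  fDisc <- volumeFraction(lat, "mitochondria")
  expect_gt(fDisc, 0.4 * 0.09 / 2)  # 400/2000 of the 9-12% band
  expect_lt(fDisc, 0.4 * 0.12 / 2 * 2)
  nDisc <- sum(lat@sites == SpliceCell:::.SITE_TYPES[["mitochondria"]])

  cfgN <- geometryConfig(spacing = 0.128, nGenes = 0, nSpeckles = 0,
                         nCajal = 0, erFraction = 0, golgiSheets = 0,
                         nMito = 400, mitoMode = "network", seed = 3)
  latN <- suppressWarnings(buildCell(cfgN))
  nNet <- sum(latN@sites == SpliceCell:::.SITE_TYPES[["mitochondria"]])
  # network mode keeps total mitochondrial volume within a few percent
  expect_lt(abs(nNet / (400 * 0.14404 / 0.128^3) - 1), 0.05)

  cfg0 <- smallCellConfig(nMito = 0)
  lat0 <- suppressWarnings(buildCell(cfg0))
  expect_identical(sum(lat0@sites == SpliceCell:::.SITE_TYPES[["mitochondria"]]),
                   0L)
})

test_that("speckle radii follow the constant-total-volume formula", {
  # n = 20, f = 0.10 of a 4.2-um nucleus: diameter 1.44 um; n = 50: 1.06 um
  Vn <- 4 / 3 * pi * 4.2^3
  d20 <- 2 * (3 * 0.10 * Vn / (4 * pi * 20))^(1 / 3)
  d50 <- 2 * (3 * 0.10 * Vn / (4 * pi * 50))^(1 / 3)
  expect_equal(d20, 1.437, tolerance = 1e-3)
  expect_equal(d50, 1.0585, tolerance = 1e-3)

  cfg <- geometryConfig(spacing = 0.128, nucleusOnly = TRUE, nSpeckles = 5,
                        speckleTotalFraction = 0.05, nCajal = 0, nGenes = 0)
  lat <- suppressWarnings(buildCell(cfg))
  rs <- lat@config$speckleRadiusRealized
  expect_equal(rs, (3 * 0.05 * Vn / (4 * pi * 5))^(1 / 3), tolerance = 1e-6)
  expect_equal(volumeFraction(lat, "speckle") /
                 volumeFraction(lat, "nucleoplasm"),
               0.05 / (1 - 0.05), tolerance = 0.25)
})

test_that("genes sit in the requested shell around speckle surfaces", {
  cfg <- geometryConfig(spacing = 0.128, nucleusOnly = TRUE, nGenes = 12,
                        seed = 5)
  lat <- suppressWarnings(buildCell(cfg))
  # default: within 0.02 um + one spacing of a speckle surface
  expect_true(all(lat@geneInfo$distance <= 0.02 + 0.128 + 1e-9))
  expect_true(all(lat@geneInfo$distance >= -1e-9))
  # round-robin assignment over speckles
  expect_true(all(table(lat@geneInfo$speckle) <= ceiling(12 / 20) + 1))

  # realized mean distance is monotone in the requested distance
  ds <- c(0.1, 0.3, 0.6)
  means <- vapply(ds, function(d) {
    l <- placeGenes(lat, 10, d = d, shellWidth = 0.02, seed = 8)
    mean(l@geneInfo$distance)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  # d too large for the nucleus errors
  expect_error(placeGenes(lat, 4, d = 10), "empty gene shell")
})

test_that("buildCell composes all organelles deterministically", {
  lat <- smallCell()
  tab <- siteTypeCounts(lat)
  expect_identical(sum(tab > 0), 11L)  # all 11 site types present

  # identical config + seed => bit-identical lattice
  lat2 <- suppressWarnings(buildCell(smallCellConfig()))
  expect_identical(lat@sites, lat2@sites)

  # organelle-free variant: only 8 site types (no mito/golgi/er)
  latNo <- suppressWarnings(buildCell(smallCellConfig(
    cytoplasmicOrganelles = FALSE)))
  tabNo <- siteTypeCounts(latNo)
  expect_identical(sum(tabNo > 0), 8L)
  expect_identical(unname(tabNo[c("mitochondria", "golgi", "er")]),
                   c(0L, 0L, 0L))

  # containment: nuclear bodies inside the nucleus, organelles outside it
  expect_identical(adjacencyCount(lat, "speckle", "cytoplasm"), 0L)
  expect_identical(adjacencyCount(lat, "mitochondria", "nucleoplasm"), 0L)
  expect_identical(adjacencyCount(lat, "er", "nucleoplasm"), 0L)
})

test_that("volume fractions partition the cell", {
  lat <- smallCell()
  intra <- setdiff(siteTypeNames(), "extracellular")
  fr <- vapply(intra, function(t) volumeFraction(lat, t), numeric(1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_error(volumeFraction(lat, "mystery"), "unknown site type")

  # whole-box extracellular fraction of the default cell:
  # 1 - (4/3) pi 8.9^3 / 18.432^3 = 0.5284
  cfg <- geometryConfig(spacing = 0.256, nGenes = 0, nSpeckles = 0,
                        nCajal = 0, erFraction = 0, golgiSheets = 0, nMito = 0)
  latBig <- suppressWarnings(buildCell(cfg))
  expect_equal(volumeFraction(latBig, "extracellular", of = "box"),
               1 - (4 / 3) * pi * 8.9^3 / 18.432^3, tolerance = 0.01)
})
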