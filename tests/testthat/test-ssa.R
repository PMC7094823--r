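# Oracle checks of the exact Gillespie engine against closed forms and the
# brute-force master equation.

.birthModel <- function(k = 0.5, nGenes = 10) {
  sp <- rbind(
    spRow("D", 0, "nucleoplasm", init_mode = "count", init_value = nGenes,
          init_where = "nucleoplasm"),
    spRow("X", 0, "nucleoplasm"))
  rx <- rxRow("birth", "D", NA, c("D", "X"), k, "s-1", "nucleoplasm")
  cmp <- data.frame(name = "nucleus", volume = 100,
                    site_types = "nucleoplasm")
  compartmentModel(cmp, NULL, adhocNetwork(sp, rx))
}

.bindModel <- function(n0 = 4, volume = 0.3387) {
  # kf = konG / (N_A V) ~ 0.5 s^-1 per pair at this volume
  sp <- rbind(
    spRow("A", 0, "nucleoplasm", init_mode = "count", init_value = n0,
          init_where = "nucleoplasm"),
    spRow("B", 0, "nucleoplasm", init_mode = "count", init_value = n0,
          init_where = "nucleoplasm"),
    spRow("C", 0, "nucleoplasm"))
  rx <- rbind(
    rxRow("bind", "A", "B", "C", 1.02e8, "M-1s-1", "nucleoplasm"),
    rxRow("unbind", "C", NA, c("A", "B"), 3.05, "s-1", "nucleoplasm"))
  cmp <- data.frame(name = "nucleus", volume = volume,
                    site_types = "nucleoplasm")
  compartmentModel(cmp, NULL, adhocNetwork(sp, rx))
}

test_that("pure birth matches the Poisson mean", {
  model <- .birthModel(k = 0.5, nGenes = 10)
  n <- 200
  ep <- vapply(seq_len(n), function(r)
    endpointCounts(runSSA(model, 4, seed = 1, replicate = r))[["X"]],
    numeric(1))
  mu <- 0.5 * 10 * 4  # 20
  se <- sqrt(mu / n)  # Poisson variance
  expect_lt(abs(mean(ep) - mu), 3 * se)
  expect_lt(abs(var(ep) / mu - 1), 0.35)  # Poisson variance check, loose
})

test_that("reversible binding matches the brute-force master equation", {
  model <- .bindModel(n0 = 4)
  V <- 0.3387
  kf <- 1.02e8 / (6.02214076e23 * V * 1e-15)
  kb <- 3.05
  # generator on C = 0..4 with A = B = 4 - C
  nS <- 5
  Q <- matrix(0, nS, nS)
  for (c0 in 0:4) {
    i <- c0 + 1
    if (c0 < 4) Q[i, i + 1] <- kf * (4 - c0)^2
    if (c0 > 0) Q[i, i - 1] <- kb * c0
    Q[i, i] <- -sum(Q[i, ])
  }
  p0 <- c(1, 0, 0, 0, 0)
  pt <- as.numeric(p0 %*% Matrix::expm(Q * 1.0))

  n <- 2000
  ep <- vapply(seq_len(n), function(r)
    endpointCounts(runSSA(model, 1.0, seed = 7, replicate = r))[["C"]],
    numeric(1))
  phat <- tabulate(ep + 1, nbins = nS) / n
  tv <- 0.5 * sum(abs(phat - pt))
  expect_lt(tv, 0.02)
})

test_that("degenerate runs behave: zero duration, determinism, empty propensity", {
  model <- .bindModel()
  t0 <- runSSA(model, 0, seed = 3)
  expect_identical(unname(endpointCounts(t0)[c("A", "B", "C")]),
                   c(4, 4, 0))
  a <- runSSA(model, 0.5, seed = 11, replicate = 2)
  b <- runSSA(model, 0.5, seed = 11, replicate = 2)
  expect_identical(a@counts, b@counts)
  c2 <- runSSA(model, 0.5, seed = 11, replicate = 3)
  expect_false(identical(a@counts, c2@counts))
})

test_that("exchange equilibrium obeys the partition closed form", {
  sp <- spRow("X", 0, "nucleoplasm,speckle", init_mode = "count",
              init_value = 400, init_where = "nucleoplasm")
  net <- adhocNetwork(sp, rxRow("noop", "X", NA, "X", 0, "s-1",
                                "nucleoplasm"))
  Vn <- 100; Vs <- 5
  rho <- 10
  k <- deriveExchangeRates(D = 1, Pn = 1, Ps = 1 / rho, area = 20,
                           lambda = 0.1, nucleoplasmVolume = Vn,
                           speckleVolume = Vs)
  expect_equal(k[["kIn"]] / k[["kOut"]], rho * Vs / Vn, tolerance = 1e-12)
  cmp <- data.frame(name = c("nucleoplasm", "speckle"), volume = c(Vn, Vs),
                    site_types = c("nucleoplasm", "speckle"))
  ex <- data.frame(species = "X", from = c("nucleoplasm", "speckle"),
                   to = c("speckle", "nucleoplasm"),
                   rate = c(k[["kIn"]], k[["kOut"]]),
                   convert_to = "X")
  model <- compartmentModel(cmp, ex, net)
  fExp <- rho * Vs / (rho * Vs + Vn)
  nRep <- 30
  f <- vapply(seq_len(nRep), function(r) {
    traj <- runSSA(model, 60, seed = 5, replicate = r)
    e <- traj@counts[1, , dim(traj@counts)[3]]
    e[2] / sum(e)
  }, numeric(1))
  se <- sd(f) / sqrt(nRep)
  expect_lt(abs(mean(f) - fExp), 3 * se + 1e-3)

  # Pn = Ps: fraction is the volume share
  kEq <- deriveExchangeRates(1, 1, 1, 20, 0.1, Vn, Vs)
  expect_equal(kEq[["kIn"]] / kEq[["kOut"]], Vs / Vn)
  expect_error(deriveExchangeRates(1, 1, 1, 20, 0.1, 0, Vs), "> 0")
})

test_that("fast exchange collapses to the single-compartment distribution", {
  mk <- function(split) {
    sp <- rbind(
      spRow("A", 0, "nucleoplasm", init_mode = "count", init_value = 30,
            init_where = "nucleoplasm"),
      spRow("B", 0, "nucleoplasm", init_mode = "count", init_value = 30,
            init_where = "nucleoplasm"),
      spRow("C", 0, "nucleoplasm"))
    rx <- rxRow("bind", "A", "B", "C", 5e7, "M-1s-1", "nucleoplasm,speckle")
    net <- adhocNetwork(sp, rx)
    if (!split) {
      cmp <- data.frame(name = "all", volume = 2,
                        site_types = "nucleoplasm,speckle")
      return(compartmentModel(cmp, NULL, net))
    }
    cmp <- data.frame(name = c("left", "right"), volume = c(1, 1),
                      site_types = c("nucleoplasm", "speckle"))
    ex <- do.call(rbind, lapply(c("A", "B", "C"), function(s)
      data.frame(species = s, from = c("left", "right"),
                 to = c("right", "left"), rate = 2000, convert_to = s)))
    compartmentModel(cmp, ex, net)
  }
  n <- 150
  one <- vapply(seq_len(n), function(r)
    endpointCounts(runSSA(mk(FALSE), 0.4, seed = 21, replicate = r))[["C"]],
    numeric(1))
  two <- vapply(seq_len(n), function(r)
    endpointCounts(runSSA(mk(TRUE), 0.4, seed = 22, replicate = r))[["C"]],
    numeric(1))
  expect_gt(suppressWarnings(ks.test(one, two))$p.value, 0.01)
})

test_that("snRNA mass balance holds exactly in the formation network", {
  model <- formationCompartmentModel()
  traj <- runSSA(model, 20, seed = 13)
  e <- endpointCounts(traj)
  transcribed <- sum(traj@tally[grepl("transcription_U1", names(traj@tally))])
  inSystem <- sum(e[c("U1snRNA_nuc", "U1snRNA_cyt", "U1snRNA_G5",
                      "U1snRNA_Sm5", "U1snRNA_Sm7", "U1snRNA_Sm7_nuc",
                      "U1snRNP")])
  expect_identical(unname(transcribed), unname(inSystem))
})
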