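test_that("worlds are deterministic under a fixed seed and differ across seeds", {
  w1 <- buildWorld(nLat = 6, nLon = 8, nCountries = 4, seed = 7)
  w2 <- buildWorld(nLat = 6, nLon = 8, nCountries = 4, seed = 7)
  expect_identical(emissionValues(w1), emissionValues(w2))
  expect_identical(w1@transfer@kernels, w2@transfer@kernels)
  expect_identical(w1@mask@assignment, w2@mask@assignment)
  w3 <- buildWorld(nLat = 6, nLon = 8, nCountries = 4, seed = 8)
  expect_false(sum(emissionValues(w3)) == sum(emissionValues(w1)))
})

test_that("invalid world configurations are rejected", {
  expect_error(buildWorld(nLat = 0), "invalid configuration")
  expect_error(buildWorld(nLat = 4, nLon = 4, nCountries = 17),
               "more countries than grid cells")
})

test_that("every country owns at least one cell and the mask partitions cells", {
  w <- sharedWorld()
  assign <- cellCountry(w@mask)
  expect_length(assign, nCells(w))
  expect_setequal(unique(assign[!is.na(assign)]), countries(w))
})

test_that("country-aggregated emissions conserve the global total", {
  w <- sharedWorld()
  E <- emissionValues(w)
  perCountry <- vapply(countries(w), function(cn)
    sum(E[cellCountry(w@mask) == cn, , ]), numeric(1))
  expect_equal(sum(perCountry), sum(E), tolerance = 1e-12)
})

test_that("agriculture emits no O3 precursor species", {
  E <- emissionValues(sharedWorld())
  expect_true(all(E[, POLLUTANT_SPECIES$O3, "AGR"] == 0))
})

test_that("surrogate cost matches a hand-computed two-cell closed form", {
  # E = (1, 2), kernel = (3, 4), background = 5, no quadratic -> 5+3+8 = 16
  w <- makeQuadraticWorld(k = c(3, 4), gamma = c(0, 0), eAnth = c(1, 2),
                          background = 5)
  expect_equal(surrogateCost(w@transfer, w@emissions, "AAA", "O3"), 16)
})

test_that("zero emissions return the background and linear species scale linearly", {
  w <- sharedWorld()
  E0 <- emissionValues(w); E0[] <- 0
  for (r in receptors(w)[1:2]) for (p in POLLUTANTS)
    expect_equal(surrogateCost(w@transfer, E0, r, p),
                 w@transfer@background[r, p])
  # doubling all emissions of linear-only species doubles their share of J
  E <- emissionValues(w)
  r <- receptors(w)[1]
  linSpecies <- setdiff(SPECIES, "NOx")
  E2 <- E; E2[, linSpecies, ] <- 2 * E2[, linSpecies, ]
  j1 <- surrogateCost(w@transfer, E, r, "O3")
  j2 <- surrogateCost(w@transfer, E2, r, "O3")
  bg <- w@transfer@background[r, "O3"]
  quadAndNOx <- sum(w@transfer@kernels$O3[r, , "NOx"] * rowSums(E[, "NOx", ])) +
    sum(w@transfer@gamma[r, ] * rowSums(E[, "NOx", ])^2)
  expect_equal(j2 - bg - quadAndNOx, 2 * (j1 - bg - quadAndNOx),
               tolerance = 1e-12)
})

test_that("grid mismatch raises a dimension error", {
  w <- sharedWorld()
  Ebad <- emissionValues(w)[1:10, , ]
  expect_error(surrogateCost(w@transfer, Ebad, receptors(w)[1]), "dimension")
})

test_that("analytic sensitivities match central finite differences", {
  w <- sharedWorld()
  E <- emissionValues(w)
  r <- receptors(w)[2]
  for (p in POLLUTANTS) {
    lam <- surrogateSensitivity(w@transfer, E, r, p)@values
    cells <- c(1L, 57L, 190L)
    for (cc in cells) for (sp in c("NOx", "SO2", "VOC")) {
      e0 <- sum(E[cc, sp, ])
      h <- max(e0, 1) * 1e-3
      Ep <- E; Ep[cc, sp, "TRN"] <- Ep[cc, sp, "TRN"] + h
      Em <- E; Em[cc, sp, "TRN"] <- Em[cc, sp, "TRN"] - h
      fd <- (surrogateCost(w@transfer, Ep, r, p) -
               surrogateCost(w@transfer, Em, r, p)) / (2 * h)
      expect_equal(unname(lam[cc, sp]), fd, tolerance = 1e-6)
    }
  }
})

test_that("sensitivity of linear species is emission-independent; gamma=0 gives the kernel", {
  w <- sharedLinearWorld()
  E <- emissionValues(w)
  r <- receptors(w)[1]
  lam1 <- surrogateSensitivity(w@transfer, E, r, "O3")@values
  lam2 <- surrogateSensitivity(w@transfer, 3 * E, r, "O3")@values
  expect_identical(lam1, lam2)
  expect_identical(lam1, w@transfer@kernels$O3[r, , ])
})

test_that("scenario runs perturb only what they claim", {
  w <- sharedWorld()
  sc <- surrogateScenarioRuns(w@transfer, w@emissions)
  E <- emissionValues(w)
  r <- receptors(w)[3]
  # N equals the surrogate with anthropogenic emissions zeroed
  EN <- E; EN[, , ANTHRO_SECTORS] <- 0
  expect_equal(sc@J[r, "O3", "N"], surrogateCost(w@transfer, EN, r, "O3"))
  # PM25 is NOx-linear, so Z and D displacements relate by the perturbation sizes:
  # D - T doubles anthropogenic NOx (+1.0), Z - T removes 90% (-0.9)
  dD <- sc@J[r, "PM25", "D"] - sc@J[r, "PM25", "T"]
  dZ <- sc@J[r, "PM25", "Z"] - sc@J[r, "PM25", "T"]
  expect_equal(dD, -dZ / 0.9, tolerance = 1e-10)
})

test_that("natural-free world with zero background has J_N = 0; null Z-perturbation is exact", {
  w <- makeQuadraticWorld(k = c(1, 2), gamma = c(0.1, -0.02),
                          eAnth = c(0.5, 1), eNat = 0)
  sc <- surrogateScenarioRuns(w@transfer, w@emissions)
  expect_equal(sc@J["AAA", "O3", "N"], 0)
  # no anthropogenic NOx at all -> Z equals T
  w2 <- makeQuadraticWorld(k = 1, gamma = 0.1, eAnth = 0, eNat = 0.4)
  sc2 <- surrogateScenarioRuns(w2@transfer, w2@emissions)
  expect_equal(sc2@J["AAA", "O3", "Z"], sc2@J["AAA", "O3", "T"])
})

test_that("curvature keeps base-state NOx sensitivities positive with a minority of concave cells", {
  w <- sharedWorld()
  E <- emissionValues(w)
  gam <- w@transfer@gamma
  expect_true(any(gam < 0))
  expect_lte(mean(gam < 0), 0.25)
  for (r in receptors(w)) {
    lam <- surrogateSensitivity(w@transfer, E, r, "O3")@values
    expect_true(all(lam[, "NOx"] > 0))
  }
})

test_that("health tables reproduce the COPD slope and monotone look-up curves", {
  ht <- buildHealthTables(c("AAA", "BBB"), seed = 3)
  expect_equal(exp(ht@beta * 10), 1.06)
  expect_equal(ht@tmrelLow, 29.1)
  expect_equal(ht@tmrelHigh, 35.7)
  for (o in PM25_OUTCOMES) {
    tab <- ht@rrLookup[[o]]
    expect_equal(tab$rr[1], 1)  # reference exposure
    probes <- sort(runif(1000, 0, 120))
    rrs <- pm25RelativeRisk(probes, tab)
    expect_true(all(diff(rrs) >= -1e-12))
  }
})
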