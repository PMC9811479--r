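test_that("scenario emission changes target only the requested sources", {
  w <- sharedWorld()
  E <- emissionValues(w)
  # unit multiplier: no change anywhere
  expect_true(all(applyScenario(E, w@mask, "TRN", multiplier = 1) == 0))
  # global 50% transport cut
  dE <- applyScenario(E, w@mask, "TRN", multiplier = 0.5)
  expect_equal(dE[, , "TRN"], 0.5 * E[, , "TRN"], tolerance = 1e-15)
  expect_true(all(dE[, , setdiff(SECTORS, "TRN")] == 0))
  # DOM case: only the named country's cells
  cn <- countries(w)[2]
  dDom <- applyScenario(E, w@mask, "TRN", 0.5, countries = cn)
  foreign <- cellCountry(w@mask) != cn
  expect_true(all(dDom[foreign, , ] == 0))
  expect_equal(dDom[!foreign, , "TRN"], 0.5 * E[!foreign, , "TRN"])
  # natural sector is untouchable; unknown names rejected
  expect_error(applyScenario(E, w@mask, "NAT"), "natural")
  expect_error(applyScenario(E, w@mask, "XXX"), "unknown sector")
  expect_error(applyScenario(E, w@mask, "TRN", countries = "ZZZ"),
               "unknown country")
})

test_that("projected exposure changes are first-order linear", {
  w <- sharedWorld()
  E <- emissionValues(w)
  r <- receptors(w)[1]
  lam <- surrogateSensitivity(w@transfer, E, r, "PM25")
  expect_equal(projectExposureChange(lam, E * 0), 0)
  d50 <- applyScenario(E, w@mask, "TRN", 0.5)
  d75 <- applyScenario(E, w@mask, "TRN", 0.25)
  expect_equal(projectExposureChange(lam, d75),
               1.5 * projectExposureChange(lam, d50), tolerance = 1e-12)
})

test_that("on a linear surrogate the projection equals a forward rerun exactly", {
  w <- sharedLinearWorld()
  E <- emissionValues(w)
  dE <- applyScenario(E, w@mask, c("TRN", "ENE"), 0.5)
  for (r in receptors(w)[1:3]) for (p in POLLUTANTS) {
    lam <- surrogateSensitivity(w@transfer, E, r, p)
    dJ <- projectExposureChange(lam, dE)
    truth <- surrogateCost(w@transfer, E, r, p) -
      surrogateCost(w@transfer, E - dE, r, p)
    expect_equal(dJ, truth, tolerance = 1e-12)
  }
})

test_that("disjoint-sector scenario benefits add at the exposure scale", {
  w <- sharedWorld()
  E <- emissionValues(w)
  r <- receptors(w)[2]
  lam <- surrogateSensitivity(w@transfer, E, r, "O3")
  dTRN <- applyScenario(E, w@mask, "TRN", 0.5)
  dENE <- applyScenario(E, w@mask, "ENE", 0.5)
  dBoth <- applyScenario(E, w@mask, c("TRN", "ENE"), 0.5)
  expect_equal(projectExposureChange(lam, dTRN) +
                 projectExposureChange(lam, dENE),
               projectExposureChange(lam, dBoth), tolerance = 1e-12)
})

test_that("net-zero ramp yields the stated remaining fractions", {
  expect_equal(netzeroMultiplier(2070), 0.6)   # 30/50 remaining, 0.4 cut
  expect_equal(netzeroMultiplier(2060), 0.5)   # 20/40 remaining
  expect_equal(netzeroMultiplier(2040), 0)     # boundary: full reduction
  expect_equal(netzeroMultiplier(2030), 0)     # past targets clip at 0
  expect_error(netzeroMultiplier(2020), "after the base year")
  # earlier targets never reduce less
  years <- seq(2035, 2090, by = 5)
  expect_true(all(diff(netzeroMultiplier(years)) >= 0))
})

test_that("DOM never exceeds ALL and their gap is the foreign-action benefit", {
  w <- sharedWorld()
  ht <- buildHealthTables(countries(w), seed = 43)
  suite <- runScenarioSuite(w, ht, sectors = "TRN", multiplier = 0.5,
                            year = 2040)
  wide <- reshape(suite, idvar = c("receptor", "pollutant"),
                  timevar = "case", direction = "wide")
  expect_true(all(wide$deathsAvoided.ALL >= wide$deathsAvoided.DOM - 1e-12))
  expect_true(all(wide$deltaExposure.ALL >= wide$deltaExposure.DOM - 1e-12))
  # decomposition at the exposure scale: ALL - DOM = foreign-cell change
  E <- emissionValues(w)
  r <- receptors(w)[1]
  foreign <- setdiff(countries(w), r)
  for (p in POLLUTANTS) {
    lam <- surrogateSensitivity(w@transfer, E, r, p)
    dFor <- applyScenario(E, w@mask, "TRN", 0.5, countries = foreign)
    gap <- wide$deltaExposure.ALL[wide$receptor == r & wide$pollutant == p] -
      wide$deltaExposure.DOM[wide$receptor == r & wide$pollutant == p]
    expect_equal(gap, projectExposureChange(lam, dFor), tolerance = 1e-10)
  }
})

test_that("a one-country world has DOM identical to ALL; a null cut avoids nothing", {
  w1 <- buildWorld(nLat = 4, nLon = 4, nCountries = 1, seed = 5)
  ht <- buildHealthTables(countries(w1), seed = 6)
  suite <- runScenarioSuite(w1, ht)
  wide <- reshape(suite, idvar = c("receptor", "pollutant"),
                  timevar = "case", direction = "wide")
  expect_equal(wide$deathsAvoided.ALL, wide$deathsAvoided.DOM,
               tolerance = 1e-12)
  null <- runScenarioSuite(w1, ht, multiplier = 1)
  expect_true(all(null$deathsAvoided == 0))
  expect_true(all(null$deltaExposure == 0))
})

test_that("the net-zero scenario reduces energy emissions along the ramp", {
  w <- buildWorld(nLat = 6, nLon = 8, nCountries = 3, seed = 9)
  ht <- buildHealthTables(countries(w), seed = 10)
  targets <- setNames(c(2050, 2060, 2070), countries(w))
  res <- runNetzeroScenario(w, ht, targets, year = 2040)
  expect_true(all(res$deathsAvoided >= 0))
  # the earliest target country reduces the most of its own ENE emissions
  E <- emissionValues(w)
  early <- countries(w)[1]
  dE <- applyScenario(E, w@mask, "ENE",
                      multiplier = netzeroMultiplier(2050),
                      countries = early)
  own <- cellCountry(w@mask) == early
  expect_equal(sum(dE[own, , "ENE"]), (1 - 1 / 3) * sum(E[own, , "ENE"]),
               tolerance = 1e-12)
})
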