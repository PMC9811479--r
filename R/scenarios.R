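#' Emission change from a reduction scenario
#'
#' Builds the emission-change field dE = (1 - multiplier) * E on the
#' affected cells, sectors and species, zero elsewhere. The natural (NAT)
#' pseudo-sector is never touched. `countries = NULL` affects every cell
#' (the ALL case); a country subset restricts the cut to those countries'
#' cells (the DOM case uses a single country).
#'
#' @param E emission values array [cell, species, sector] or an
#'   \linkS4class{EmissionField}
#' @param mask a \linkS4class{RegionMask}
#' @param sectors sectors to cut (anthropogenic only)
#' @param multiplier remaining-emission fraction in [0, 1]; 0.5 means a
#'   50 % cut
#' @param countries country codes whose cells are affected, or NULL for all
#' @param species species to cut, default all
#' @return dE array [cell, species, sector]
#' @export
applyScenario <- function(E, mask, sectors = "TRN", multiplier = 0.5,
                          countries = NULL, species = SPECIES) {
  if (is(E, "EmissionField")) E <- E@values
  if ("NAT" %in% sectors)
    stop("validation error: the natural sector cannot be cut")
  if (!all(sectors %in% ANTHRO_SECTORS))
    stop("validation error: unknown sector(s): ",
         paste(setdiff(sectors, ANTHRO_SECTORS), collapse = ", "))
  if (!all(species %in% SPECIES))
    stop("validation error: unknown species")
  if (multiplier < 0 || multiplier > 1)
    stop("validation error: multiplier must lie in [0, 1]")
  dE <- array(0, dim = dim(E), dimnames = dimnames(E))
  cells <- if (is.null(countries)) seq_len(dim(E)[1]) else {
    if (!all(countries %in% mask@countries))
      stop("validation error: unknown country: ",
           paste(setdiff(countries, mask@countries), collapse = ", "))
    which(cellCountry(mask) %in% countries)
  }
  dE[cells, species, sectors] <- (1 - multiplier) * E[cells, species, sectors]
  dE
}

#' First-order exposure change from an emission change
#'
#' dJ = sum(lambda * dE): the sensitivity-projected exposure response to a
#' scenario's emission change (first order only).
#'
#' @param sens a \linkS4class{SensitivityField} or [cell, species] matrix
#' @param dE emission-change array [cell, species, sector]
#' @return exposure change for the sensitivity's receptor
#' @export
projectExposureChange <- function(sens, dE) {
  lam <- if (is(sens, "SensitivityField")) sens@values else sens
  if (!identical(dim(lam), dim(dE)[1:2]))
    stop("dimension error: sensitivity and emission change must share axes")
  sum(firstOrderContribution(lam, dE))
}

#' Net-zero remaining-emission fraction
#'
#' Linear decarbonization ramp from the base year to a country's net-zero
#' target year: the fraction of energy-sector emissions remaining at the
#' horizon is (target - horizon) / (target - base), clipped to [0, 1].
#' Earlier targets give larger reductions; a target at or before the
#' horizon gives full reduction. The energy-sector reduction to apply is
#' 1 - fraction.
#'
#' @param targetYear net-zero target year (> baseYear)
#' @param horizonYear assessment year (default 2040)
#' @param baseYear ramp start (default 2020)
#' @return remaining-emission fraction in [0, 1]
#' @export
netzeroMultiplier <- function(targetYear, horizonYear = 2040,
                              baseYear = 2020) {
  if (any(targetYear <= baseYear))
    stop("validation error: target year must be after the base year")
  pmin(1, pmax(0, (targetYear - horizonYear) / (targetYear - baseYear)))
}

#' Deaths avoided under an emission-change field
#'
#' Projects the exposure change per receptor and pollutant and converts it
#' to deaths avoided by exposure differencing against the base-state
#' surrogate exposures.
#' @keywords internal
scenarioDeaths <- function(world, tables, dE, year) {
  rec <- receptors(world)
  rows <- lapply(rec, function(r) {
    out <- lapply(POLLUTANTS, function(p) {
      lam <- surrogateSensitivity(world@transfer, world@emissions, r, p)
      dJ <- projectExposureChange(lam, dE)
      base <- surrogateCost(world@transfer, world@emissions, r, p)
      deaths <- sourceHealthImpact(base, base - dJ, tables, p, r, year)
      data.frame(receptor = r, pollutant = p, deltaExposure = dJ,
                 deathsAvoided = deaths)
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Run the DOM/ALL scenario suite
#'
#' For every receptor, computes deaths avoided under the DOM case (only the
#' receptor cuts its emissions) and the ALL case (every country cuts),
#' their ratio, and the foreign-action benefit ALL - DOM, per pollutant.
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param tables a \linkS4class{HealthTables}
#' @param sectors sectors to cut (default TRN)
#' @param multiplier remaining-emission fraction (default 0.5, a 50 % cut)
#' @param year demographics year used for the health step (default 2040,
#'   using projected population and baseline rates)
#' @return data.frame (receptor, pollutant, case, deltaExposure,
#'   deathsAvoided) with cases DOM and ALL
#' @export
runScenarioSuite <- function(world, tables, sectors = "TRN",
                             multiplier = 0.5, year = 2040) {
  E <- emissionValues(world)
  dAll <- applyScenario(E, world@mask, sectors, multiplier, countries = NULL)
  all <- scenarioDeaths(world, tables, dAll, year)
  all$case <- "ALL"
  dom <- do.call(rbind, lapply(receptors(world), function(r) {
    dDom <- applyScenario(E, world@mask, sectors, multiplier, countries = r)
    d <- scenarioDeaths(world, tables, dDom, year)
    d[d$receptor == r, ]
  }))
  dom$case <- "DOM"
  out <- rbind(dom, all)
  rownames(out) <- NULL
  out[order(out$receptor, out$pollutant, out$case), ]
}

#' Net-zero energy co-benefit scenario
#'
#' Applies each country's net-zero ramp reduction to its energy-sector
#' emissions (air-pollutant cuts scale linearly with the CO2 cut, energy
#' sector only, no replacement-energy emissions added) and returns deaths
#' avoided per source country and receptor.
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param tables a \linkS4class{HealthTables}
#' @param targetYears named numeric vector, net-zero target year per
#'   country code
#' @param year assessment year
#' @return data.frame (source, receptor, pollutant, deathsAvoided)
#' @export
runNetzeroScenario <- function(world, tables, targetYears, year = 2040) {
  E <- emissionValues(world)
  rows <- lapply(names(targetYears), function(src) {
    remain <- netzeroMultiplier(targetYears[[src]], horizonYear = year)
    dE <- applyScenario(E, world@mask, sectors = "ENE",
                        multiplier = remain, countries = src)
    d <- scenarioDeaths(world, tables, dE, year)
    data.frame(source = src, d)
  })
  do.call(rbind, rows)
}
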