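#' @import methods
NULL

#' Chemical species tracked by the framework
#'
#' Seven precursor species: primary carbonaceous aerosol (BC, OC), ammonia,
#' nitrogen oxides, sulfur dioxide, volatile organic compounds and carbon
#' monoxide.
#' @export
SPECIES <- c("BC", "OC", "NH3", "NOx", "SO2", "VOC", "CO")

#' Emission sectors
#'
#' The seven HTAP-style anthropogenic sectors (aviation, agriculture, energy
#' generation, industry, residential, shipping, land transportation) plus a
#' NAT pseudo-sector holding natural emissions, which provides the natural
#' floor required by the natural-only forward-model state.
#' @export
SECTORS <- c("AIR", "AGR", "ENE", "IND", "RES", "SHP", "TRN", "NAT")

#' @rdname SECTORS
#' @export
ANTHRO_SECTORS <- setdiff(SECTORS, "NAT")

#' Pollutants
#'
#' The two exposure metrics: annual-average population-weighted PM2.5
#' (ug/m3) and 6-month peak daily-maximum 8-hour-average O3 (ppb).
#' @export
POLLUTANTS <- c("PM25", "O3")

#' Precursor species entering each pollutant's cost function
#' @export
POLLUTANT_SPECIES <- list(
  PM25 = c("BC", "OC", "NH3", "NOx", "SO2"),
  O3   = c("NOx", "VOC", "CO")
)

#' Regular latitude-longitude grid
#'
#' Cell centers, latitude ascending, longitudes in [-180, 180). Cells are
#' indexed 1..nCells in row-major order (longitude fastest).
#'
#' @slot latEdges ascending latitude cell edges (degrees)
#' @slot lonEdges ascending longitude cell edges (degrees)
#' @export
setClass("WorldGrid", representation(latEdges = "numeric", lonEdges = "numeric"))

setValidity("WorldGrid", function(object) {
  if (length(object@latEdges) < 2L || length(object@lonEdges) < 2L)
    return("grid needs at least one cell in each dimension")
  if (any(diff(object@latEdges) <= 0) || any(diff(object@lonEdges) <= 0))
    return("grid edges must be strictly ascending")
  TRUE
})

#' Country mask on a grid
#'
#' Whole-cell assignment of grid cells to country codes; NA marks an
#' unassigned cell. Fractional border cells are deliberately not modelled.
#'
#' @slot assignment character vector, one country code (or NA) per cell
#' @slot countries the country code list; every code owns at least one cell
#' @export
setClass("RegionMask", representation(assignment = "character", countries = "character"))

setValidity("RegionMask", function(object) {
  owned <- unique(object@assignment[!is.na(object@assignment)])
  if (!all(object@countries %in% owned))
    return("every country in the country list must own at least one cell")
  if (!all(owned %in% object@countries))
    return("assignment refers to a country absent from the country list")
  if (anyDuplicated(object@countries))
    return("duplicated country codes")
  TRUE
})

#' Gridded sectoral emissions
#'
#' @slot values nonnegative array [cell, species, sector] in Tg/yr, with
#'   dimnames on the species and sector axes
#' @export
setClass("EmissionField", representation(values = "array"))

setValidity("EmissionField", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("emission values must be a [cell, species, sector] array")
  if (!identical(dimnames(v)[[2]], SPECIES))
    return("species axis must carry the canonical species names")
  if (!all(dimnames(v)[[3]] %in% SECTORS))
    return("unknown sector name on the sector axis")
  if (any(!is.finite(v)) || any(v < 0))
    return("emissions must be finite and nonnegative")
  TRUE
})

#' Analytic surrogate transfer model
#'
#' Stands in for a chemical-transport forward/adjoint model. Each receptor
#' country's exposure cost function is the closed form
#' J = background + sum(kernel * E) + sum(gamma * E_NOx^2) (the quadratic
#' term applies to the O3 pathway only), so gradients and scenario outputs
#' are exact.
#'
#' @slot kernels list per pollutant of arrays [receptor, cell, species]
#'   (exposure units per Tg/yr); population weighting is folded in
#' @slot gamma matrix [receptor, cell] of O3-NOx curvatures (exposure units
#'   per (Tg/yr)^2); small negative entries emulate titration-like cells
#' @slot background matrix [receptor, pollutant], exposure units
#' @slot receptors receptor country codes
#' @export
setClass("SurrogateTransfer", representation(
  kernels = "list", gamma = "matrix", background = "matrix",
  receptors = "character"))

setValidity("SurrogateTransfer", function(object) {
  if (!all(POLLUTANTS %in% names(object@kernels)))
    return("kernels must be keyed by pollutant")
  for (p in POLLUTANTS) {
    k <- object@kernels[[p]]
    if (length(dim(k)) != 3L || dim(k)[1] != length(object@receptors))
      return("each kernel must be [receptor, cell, species]")
  }
  if (!identical(dim(object@gamma)[1], length(object@receptors)))
    return("gamma must have one row per receptor")
  if (any(!is.finite(object@background)))
    return("background must be finite")
  TRUE
})

#' A self-consistent synthetic study domain
#'
#' Grid, country mask, population, sectoral emissions and the analytic
#' surrogate transfer model, generated deterministically from a seed.
#'
#' @slot grid a \linkS4class{WorldGrid}
#' @slot mask a \linkS4class{RegionMask}
#' @slot population persons per cell
#' @slot emissions an \linkS4class{EmissionField}
#' @slot transfer a \linkS4class{SurrogateTransfer}
#' @slot seed the generating seed
#' @export
setClass("SyntheticWorld", representation(
  grid = "WorldGrid", mask = "RegionMask", population = "numeric",
  emissions = "EmissionField", transfer = "SurrogateTransfer",
  seed = "integer"))

setValidity("SyntheticWorld", function(object) {
  n <- nCells(object@grid)
  if (length(object@mask@assignment) != n) return("mask does not match grid")
  if (length(object@population) != n) return("population does not match grid")
  if (dim(object@emissions@values)[1] != n) return("emissions do not match grid")
  if (any(object@population < 0)) return("population must be nonnegative")
  TRUE
})

#' Adjoint-style sensitivity field
#'
#' Gradient of one receptor's cost function with respect to gridded
#' precursor emissions, evaluated at a given emission state.
#'
#' @slot values matrix [cell, species], exposure units per Tg/yr
#' @slot receptor receptor country code
#' @slot pollutant "PM25" or "O3"
#' @export
setClass("SensitivityField", representation(
  values = "matrix", receptor = "character", pollutant = "character"))

setValidity("SensitivityField", function(object) {
  if (!identical(colnames(object@values), SPECIES))
    return("sensitivity columns must be the canonical species")
  if (!object@pollutant %in% POLLUTANTS) return("unknown pollutant")
  TRUE
})

#' Cost-function values for the four forward-model states
#'
#' Base (T), natural-only (N), 10 % anthropogenic NOx (Z) and doubled
#' anthropogenic NOx (D).
#'
#' @slot J array [receptor, pollutant, state] with states T, N, Z, D
#' @export
setClass("ScenarioOutputs", representation(J = "array"))

setValidity("ScenarioOutputs", function(object) {
  if (!identical(dimnames(object@J)[[3]], c("T", "N", "Z", "D")))
    return("states must be T, N, Z, D")
  TRUE
})

#' Source-attribution result
#'
#' Exposure contributions resolved by receptor, source country, sector and
#' species for one pollutant; contributions from unassigned cells are kept
#' separately so aggregation conserves totals.
#'
#' @slot values array [receptor, source, sector, species], exposure units
#' @slot pollutant "PM25" or "O3"
#' @slot unassigned array [receptor, sector, species]
#' @export
setClass("ContributionTensor", representation(
  values = "array", pollutant = "character", unassigned = "array"))

setValidity("ContributionTensor", function(object) {
  if (length(dim(object@values)) != 4L)
    return("values must be [receptor, source, sector, species]")
  if (any(!is.finite(object@values))) return("contributions must be finite")
  if (!object@pollutant %in% POLLUTANTS) return("unknown pollutant")
  TRUE
})

#' Fitted per-cell quadratic O3-NOx response coefficients
#'
#' One (c1, c2, c3) triple per cell for one receptor, with the numerical
#' rank used by the pseudoinverse solve.
#'
#' @slot coef matrix [cell, 3] with columns c1, c2, c3
#' @slot rank integer rank used per cell
#' @slot cells grid cell indices the fit covers
#' @slot receptor receptor country code
#' @export
setClass("QuadraticFit", representation(
  coef = "matrix", rank = "integer", cells = "integer", receptor = "character"))

setValidity("QuadraticFit", function(object) {
  if (ncol(object@coef) != 3L) return("coef must have columns c1, c2, c3")
  if (nrow(object@coef) != length(object@cells)) return("one row per cell required")
  TRUE
})

#' GBD-style health input tables
#'
#' @slot rrLookup named list (one PM2.5 outcome each) of data.frames with
#'   strictly increasing `exposure` (ug/m3) and non-decreasing `rr`
#' @slot beta log-RR slope for the O3-COPD log-linear model (per ppb)
#' @slot tmrelLow,tmrelHigh bounds of the uniform TMREL distribution (ppb)
#' @slot demographics data.frame (country, outcome, year, pop, y0);
#'   y0 in deaths per person-year
#' @slot foresight data.frame (country, outcome, year, rate) on 5-year
#'   increments 2015..2040, used for mortality-rate projection
#' @export
setClass("HealthTables", representation(
  rrLookup = "list", beta = "numeric", tmrelLow = "numeric",
  tmrelHigh = "numeric", demographics = "data.frame", foresight = "data.frame"))

setValidity("HealthTables", function(object) {
  for (nm in names(object@rrLookup)) {
    tab <- object@rrLookup[[nm]]
    if (!all(c("exposure", "rr") %in% names(tab)))
      return("look-up tables need exposure and rr columns")
    if (any(diff(tab$exposure) <= 0))
      return("look-up exposures must be strictly increasing")
    if (any(tab$rr < 1) || any(diff(tab$rr) < 0))
      return("look-up RR must be >= 1 and non-decreasing")
  }
  if (object@tmrelLow >= object@tmrelHigh) return("tmrelLow must be < tmrelHigh")
  if (object@beta <= 0) return("beta must be positive")
  d <- object@demographics
  if (any(d$pop < 0) || any(d$y0 < 0))
    return("population and baseline rates must be nonnegative")
  TRUE
})
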