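#' Species profile per sector (columns sum to one)
#'
#' Agriculture emits no O3 precursor (no NOx, VOC or CO), so agricultural
#' sources never reach the O3 pathway; transport is NOx-dominated, energy
#' SO2/NOx, residential carbonaceous, and the natural pseudo-sector is
#' dominated by biogenic VOC with soil NOx.
#' @keywords internal
sectorSpeciesProfile <- function() {
  p <- matrix(0, length(SPECIES), length(SECTORS),
              dimnames = list(SPECIES, SECTORS))
  p[, "AIR"] <- c(0.05, 0.05, 0.00, 0.50, 0.10, 0.10, 0.20)
  p[, "AGR"] <- c(0.00, 0.10, 0.90, 0.00, 0.00, 0.00, 0.00)
  p[, "ENE"] <- c(0.02, 0.03, 0.00, 0.40, 0.45, 0.05, 0.05)
  p[, "IND"] <- c(0.05, 0.05, 0.00, 0.25, 0.30, 0.20, 0.15)
  p[, "RES"] <- c(0.20, 0.35, 0.00, 0.02, 0.03, 0.10, 0.30)
  p[, "SHP"] <- c(0.05, 0.05, 0.00, 0.50, 0.35, 0.00, 0.05)
  p[, "TRN"] <- c(0.05, 0.00, 0.00, 0.60, 0.00, 0.10, 0.25)
  p[, "NAT"] <- c(0.00, 0.05, 0.025, 0.10, 0.025, 0.60, 0.20)
  p
}

# Global sector totals, Tg/yr; rough HTAP-like anthropogenic magnitudes.
# NAT is biogenic-dominated (VOC-heavy, soil NOx) and deliberately large:
# in the real atmosphere most background O3 is produced from natural
# precursors, so the natural-only state must be emission-driven.
.sectorTotals <- c(AIR = 1, AGR = 45, ENE = 60, IND = 50, RES = 30,
                   SHP = 10, TRN = 40, NAT = 150)

makeCountryCode <- function(i) {
  a <- LETTERS[((i - 1L) %/% 26L) %% 26L + 1L]
  b <- LETTERS[(i - 1L) %% 26L + 1L]
  paste0(a, b, LETTERS[(i * 7L) %% 26L + 1L])
}

#' Generate a synthetic study domain
#'
#' Builds a deterministic toy world: a regular grid, a whole-cell Voronoi
#' country mask, log-normal population and emissions with sector-specific
#' species profiles, and an analytic surrogate transfer model whose linear
#' kernels decay with great-circle distance from each receptor's population
#' (so upwind neighbours matter) and whose per-cell quadratic O3-NOx
#' curvature includes a minority of weakly concave, titration-like cells.
#'
#' Kernels are scaled so mean base exposures sit at realistic levels
#' (~25 ug/m3 PM2.5, ~45 ppb O3); curvature is bounded so that
#' |2*gamma*E_NOx| stays below the linear kernel at base emissions, keeping
#' base-state sensitivities positive.
#'
#' @param nLat,nLon grid dimensions
#' @param nCountries number of countries (each owns >= 1 cell)
#' @param seed integer seed; identical seeds give bit-identical worlds
#' @param curved if FALSE all quadratic curvatures are zero (purely linear
#'   surrogate), useful for linear-limit analyses
#' @param decayLength named vector, e-folding transport distance in km per
#'   pollutant; the O3 default is longer, reflecting its longer lifetime
#' @param meanExposure,background named vectors per pollutant, exposure units
#' @param negShare fraction of cells drawn with negative O3-NOx curvature
#' @return a \linkS4class{SyntheticWorld}
#' @export
buildWorld <- function(nLat = 12L, nLon = 16L, nCountries = 8L, seed = 1L,
                       curved = TRUE,
                       decayLength = c(PM25 = 900, O3 = 2600),
                       meanExposure = c(PM25 = 25, O3 = 45),
                       background = c(PM25 = 1, O3 = 5),
                       negShare = 0.15) {
  if (nLat < 1L || nLon < 1L || nCountries < 1L)
    stop("invalid configuration: dimensions and country count must be positive")
  if (nCountries > nLat * nLon)
    stop("invalid configuration: more countries than grid cells")
  set.seed(seed)

  grid <- new("WorldGrid",
              latEdges = seq(-60, 60, length.out = nLat + 1L),
              lonEdges = seq(-180, 180, length.out = nLon + 1L))
  n <- nCells(grid)
  ctr <- cellCenters(grid)

  ## Voronoi country mask around random seed cells (whole-cell assignment)
  codes <- vapply(seq_len(nCountries), makeCountryCode, character(1))
  seedCells <- sample.int(n, nCountries)
  dseed <- geosphere::distHaversine(
    ctr[rep(seq_len(n), times = nCountries), , drop = FALSE],
    ctr[rep(seedCells, each = n), , drop = FALSE]) / 1000
  dseed <- matrix(dseed, nrow = n)
  assign <- codes[max.col(-dseed, ties.method = "first")]
  mask <- new("RegionMask", assignment = assign, countries = codes)

  population <- stats::rlnorm(n, meanlog = log(2e5), sdlog = 1.2)

  ## Emissions: sector totals split across cells by population share with
  ## log-normal scatter; NAT split by cell area instead.
  prof <- sectorSpeciesProfile()
  E <- array(0, dim = c(n, length(SPECIES), length(SECTORS)),
             dimnames = list(NULL, SPECIES, SECTORS))
  area <- cellArea(grid)
  ## sector totals carry inventory-style log-normal uncertainty so worlds
  ## from different seeds differ in total emitted mass
  totals <- .sectorTotals * stats::rlnorm(length(SECTORS), 0, 0.15)
  for (s in SECTORS) {
    w <- if (s == "NAT") area * stats::rlnorm(n, 0, 0.6)
         else population^0.7 * stats::rlnorm(n, 0, 0.8)
    w <- w / sum(w)
    E[, , s] <- outer(totals[[s]] * w, prof[, s])
  }
  emissions <- new("EmissionField", values = E)

  ## Linear kernels: receptor population-weighted distance decay, per
  ## pollutant species susceptibilities.
  suscept <- list(
    PM25 = c(BC = 1.0, OC = 0.8, NH3 = 0.5, NOx = 0.3, SO2 = 0.4, VOC = 0, CO = 0),
    O3   = c(BC = 0, OC = 0, NH3 = 0, NOx = 1.0, SO2 = 0, VOC = 0.4, CO = 0.05))
  kernels <- list()
  for (p in POLLUTANTS) {
    w <- matrix(0, nCountries, n, dimnames = list(codes, NULL))
    for (i in seq_len(nCountries)) {
      inR <- which(assign == codes[i])
      popw <- population[inR] / sum(population[inR])
      d <- geosphere::distHaversine(
        ctr[rep(seq_len(n), times = length(inR)), , drop = FALSE],
        ctr[rep(inR, each = n), , drop = FALSE]) / 1000
      d <- matrix(d, nrow = n)
      w[i, ] <- as.vector(exp(-d / decayLength[[p]]) %*% cbind(popw))
    }
    k <- array(0, dim = c(nCountries, n, length(SPECIES)),
               dimnames = list(codes, NULL, SPECIES))
    for (sp in SPECIES) k[, , sp] <- w * suscept[[p]][[sp]]
    kernels[[p]] <- k
  }

  ## O3-NOx curvature, expressed relative to the linear NOx kernel so the
  ## base-state sensitivity kernel + 2*gamma*E stays positive:
  ## gamma = u * kernel / E_NOx with 2u in (-0.3, 0.7).
  eNOx <- rowSums(E[, "NOx", ])
  gamma <- matrix(0, nCountries, n, dimnames = list(codes, NULL))
  if (curved) {
    u <- ifelse(stats::runif(nCountries * n) < negShare,
                stats::runif(nCountries * n, -0.15, -0.02),
                stats::runif(nCountries * n, 0.05, 0.35))
    u <- matrix(u, nCountries, n)
    pos <- eNOx > 0
    gamma[, pos] <- u[, pos] * kernels$O3[, pos, "NOx"] /
      rep(eNOx[pos], each = nCountries)
  }

  ## Scale kernels (and gamma, which is kernel-proportional) so the mean
  ## receptor exposure hits the target level.
  bg <- matrix(rep(background[POLLUTANTS], each = nCountries),
               nCountries, length(POLLUTANTS),
               dimnames = list(codes, POLLUTANTS))
  for (p in POLLUTANTS) {
    lin <- vapply(seq_len(nCountries), function(i)
      sum(kernels[[p]][i, , ] * apply(E, c(1, 2), sum)), numeric(1))
    resp <- lin
    if (p == "O3") resp <- resp + as.vector(gamma %*% cbind(eNOx^2))
    sc <- (meanExposure[[p]] - background[[p]]) / mean(resp)
    kernels[[p]] <- kernels[[p]] * sc
    if (p == "O3") gamma <- gamma * sc
  }

  transfer <- new("SurrogateTransfer", kernels = kernels, gamma = gamma,
                  background = bg, receptors = codes)
  new("SyntheticWorld", grid = grid, mask = mask, population = population,
      emissions = emissions, transfer = transfer, seed = as.integer(seed))
}

#' Total anthropogenic NOx per cell
#' @param world a SyntheticWorld or EmissionField values array
#' @keywords internal
cellNOx <- function(E, sectors = SECTORS) {
  rowSums(E[, "NOx", sectors, drop = FALSE])
}
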