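#' First-order source contribution
#'
#' Elementwise product of an adjoint-style sensitivity with sectoral
#' emissions: the local-linear share of the receptor's cost function
#' attributed to each (cell, species, sector) source. No aggregation.
#'
#' @param sens a \linkS4class{SensitivityField} (or [cell, species] matrix)
#' @param E emission values array [cell, species, sector] or an
#'   \linkS4class{EmissionField}
#' @return array [cell, species, sector], exposure units
#' @export
firstOrderContribution <- function(sens, E) {
  lam <- if (is(sens, "SensitivityField")) sens@values else sens
  if (is(E, "EmissionField")) E <- E@values
  if (!identical(dim(lam), dim(E)[1:2]))
    stop("dimension error: sensitivity and emissions must share grid and species axes")
  out <- E
  for (s in seq_len(dim(E)[3])) out[, , s] <- lam * E[, , s]
  out
}

#' Scale contributions to match the cost function
#'
#' Multiplies all contributions for one receptor by a single scalar so
#' their sum equals the cost-function value less the configured background
#' and natural shares (the normalization is applied to the anthropogenic
#' share).
#'
#' @param contrib contribution array (any shape)
#' @param jTotal the receptor's cost-function value
#' @param background exposure not attributable to emissions
#' @param naturalShare exposure assigned to natural sources, excluded from
#'   the scaled total
#' @return contributions rescaled so sum(result) = jTotal - background -
#'   naturalShare
#' @export
normalizeContributions <- function(contrib, jTotal, background = 0,
                                   naturalShare = 0) {
  tot <- sum(contrib)
  if (tot == 0)
    stop("cannot normalize: contributions sum to zero")
  contrib * ((jTotal - background - naturalShare) / tot)
}

#' Aggregate cell contributions to source countries
#'
#' Sums cell-level contributions into (source country, sector, species)
#' bins under a whole-cell mask; contributions from unassigned cells are
#' returned separately so totals are conserved under any partition.
#'
#' @param contrib array [cell, species, sector]
#' @param mask a \linkS4class{RegionMask}
#' @return list with `bySource` [source, sector, species] and `unassigned`
#'   [sector, species]
#' @export
aggregateToSources <- function(contrib, mask) {
  cn <- countries(mask)
  assign <- cellCountry(mask)
  sp <- dimnames(contrib)[[2]]; sec <- dimnames(contrib)[[3]]
  bySource <- array(0, dim = c(length(cn), length(sec), length(sp)),
                    dimnames = list(cn, sec, sp))
  for (ci in seq_along(cn)) {
    idx <- which(assign == cn[ci])
    if (length(idx))
      bySource[ci, , ] <- t(apply(contrib[idx, , , drop = FALSE], c(2, 3), sum))
  }
  un <- which(is.na(assign))
  unassigned <- if (length(un))
    t(apply(contrib[un, , , drop = FALSE], c(2, 3), sum))
  else array(0, dim = c(length(sec), length(sp)), dimnames = list(sec, sp))
  list(bySource = bySource, unassigned = unassigned)
}

#' Full first-order attribution of a synthetic world
#'
#' For every receptor: analytic sensitivities at the base state, first-order
#' contributions, normalization of the anthropogenic share to the cost
#' function (less background and the first-order natural share), and
#' aggregation to source countries. Natural (NAT) contributions are kept in
#' the tensor's NAT sector but are excluded from the normalization target.
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param pollutant "PM25" or "O3"
#' @param normalize scale contributions to the cost function (default TRUE)
#' @return a \linkS4class{ContributionTensor}
#' @export
attributeWorld <- function(world, pollutant = "PM25", normalize = TRUE) {
  tr <- world@transfer
  rec <- receptors(world)
  cn <- countries(world@mask)
  vals <- array(0, dim = c(length(rec), length(cn), length(SECTORS), length(SPECIES)),
                dimnames = list(rec, cn, SECTORS, SPECIES))
  unass <- array(0, dim = c(length(rec), length(SECTORS), length(SPECIES)),
                 dimnames = list(rec, SECTORS, SPECIES))
  for (r in rec) {
    lam <- surrogateSensitivity(tr, world@emissions, r, pollutant)
    contrib <- firstOrderContribution(lam, world@emissions)
    if (normalize) {
      j <- surrogateCost(tr, world@emissions, r, pollutant)
      bg <- tr@background[r, pollutant]
      natShare <- sum(contrib[, , "NAT"])
      anth <- contrib[, , ANTHRO_SECTORS, drop = FALSE]
      contrib[, , ANTHRO_SECTORS] <- normalizeContributions(
        anth, j, background = bg, naturalShare = natShare)
    }
    agg <- aggregateToSources(contrib, world@mask)
    vals[r, , , ] <- agg$bySource
    unass[r, , ] <- agg$unassigned
  }
  new("ContributionTensor", values = vals, pollutant = pollutant,
      unassigned = unass)
}

#' Imported, domestic and exported totals for a receptor
#'
#' Domestic: contributions whose source country equals the receptor.
#' Imported: contributions into the receptor from all other sources.
#' Exported: contributions of the receptor's emissions into all *other*
#' modelled receptors (impacts outside the modelled receptor set are not
#' estimated). Natural (NAT) contributions are excluded throughout; signed
#' contributions from concave O3 cells are retained, not clipped.
#'
#' @param tensor a \linkS4class{ContributionTensor}
#' @param receptor receptor country code
#' @return list(imported, domestic, exported, net)
#' @export
classifyFlows <- function(tensor, receptor) {
  v <- tensor@values
  rec <- dimnames(v)[[1]]; src <- dimnames(v)[[2]]
  if (!receptor %in% rec) stop("receptor not in tensor: ", receptor)
  sec <- setdiff(dimnames(v)[[3]], "NAT")
  domestic <- if (receptor %in% src) sum(v[receptor, receptor, sec, ]) else 0
  imported <- sum(v[receptor, setdiff(src, receptor), sec, ])
  exported <- if (receptor %in% src)
    sum(v[setdiff(rec, receptor), receptor, sec, ]) else 0
  list(imported = imported, domestic = domestic, exported = exported,
       net = imported + domestic)
}

#' Response to extra-regional emission reductions
#'
#' RERER = imported / (imported + domestic): the fraction of a receptor's
#' (health) burden that originates outside its borders. Scale-invariant;
#' lies in [0, 1] for nonnegative inputs.
#'
#' @param imported,domestic burden from foreign / own sources (exposure or
#'   deaths); vectorized
#' @return fraction
#' @export
rerer <- function(imported, domestic) {
  net <- imported + domestic
  if (any(net == 0))
    stop("RERER undefined: imported + domestic is zero")
  imported / net
}

#' Flow summary table for all receptors
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param tensor a \linkS4class{ContributionTensor} (defaults to a fresh
#'   first-order attribution)
#' @return data.frame (receptor, pollutant, imported, domestic, exported,
#'   net, rerer)
#' @export
flowSummary <- function(world, tensor = attributeWorld(world)) {
  rec <- dimnames(tensor@values)[[1]]
  rows <- lapply(rec, function(r) {
    f <- classifyFlows(tensor, r)
    data.frame(receptor = r, pollutant = tensor@pollutant,
               imported = f$imported, domestic = f$domestic,
               exported = f$exported, net = f$net,
               rerer = if (f$net != 0) f$imported / f$net else NA_real_)
  })
  do.call(rbind, rows)
}
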