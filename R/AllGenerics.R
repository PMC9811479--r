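#' @rdname WorldGrid-class
#' @param x,object an object
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname WorldGrid-class
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname WorldGrid-class
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))

#' @rdname RegionMask-class
#' @export
setGeneric("countries", function(x) standardGeneric("countries"))

#' @rdname RegionMask-class
#' @export
setGeneric("cellCountry", function(x) standardGeneric("cellCountry"))

#' @rdname SurrogateTransfer-class
#' @export
setGeneric("receptors", function(x) standardGeneric("receptors"))

#' @rdname EmissionField-class
#' @export
setGeneric("emissionValues", function(x) standardGeneric("emissionValues"))

setMethod("nCells", "WorldGrid", function(x)
  (length(x@latEdges) - 1L) * (length(x@lonEdges) - 1L))

setMethod("cellCenters", "WorldGrid", function(x) {
  latc <- (x@latEdges[-1] + x@latEdges[-length(x@latEdges)]) / 2
  lonc <- (x@lonEdges[-1] + x@lonEdges[-length(x@lonEdges)]) / 2
  cbind(lon = rep(lonc, times = length(latc)),
        lat = rep(latc, each = length(lonc)))
})

setMethod("cellArea", "WorldGrid", function(x) {
  ctr <- cellCenters(x)
  dlat <- diff(x@latEdges)
  dlon <- diff(x@lonEdges)
  km_deg <- 111.32
  rep(dlat, each = length(dlon)) * km_deg *
    rep(dlon, times = length(dlat)) * km_deg * cos(ctr[, "lat"] * pi / 180)
})

setMethod("countries", "RegionMask", function(x) x@countries)
setMethod("cellCountry", "RegionMask", function(x) x@assignment)
setMethod("countries", "SyntheticWorld", function(x) x@mask@countries)
setMethod("nCells", "SyntheticWorld", function(x) nCells(x@grid))
setMethod("receptors", "SurrogateTransfer", function(x) x@receptors)
setMethod("receptors", "SyntheticWorld", function(x) x@transfer@receptors)
setMethod("emissionValues", "EmissionField", function(x) x@values)
setMethod("emissionValues", "SyntheticWorld", function(x) x@emissions@values)

setMethod("show", "WorldGrid", function(object) {
  cat(sprintf("WorldGrid: %d x %d cells (lat %g..%g, lon %g..%g)\n",
              length(object@latEdges) - 1L, length(object@lonEdges) - 1L,
              min(object@latEdges), max(object@latEdges),
              min(object@lonEdges), max(object@lonEdges)))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d cells, %d countries, seed %d\n  total emissions %.3g Tg/yr, population %.3g\n",
    nCells(object), length(countries(object)), object@seed,
    sum(object@emissions@values), sum(object@population)))
})

setMethod("show", "EmissionField", function(object) {
  v <- object@values
  cat(sprintf("EmissionField: %d cells x %d species x %d sectors, total %.4g Tg/yr\n",
              dim(v)[1], dim(v)[2], dim(v)[3], sum(v)))
})

setMethod("show", "ContributionTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ContributionTensor (%s): %d receptors x %d sources x %d sectors x %d species; total %.4g\n",
    object@pollutant, d[1], d[2], d[3], d[4], sum(object@values)))
})

setMethod("show", "SensitivityField", function(object) {
  cat(sprintf("SensitivityField (%s, receptor %s): %d cells\n",
              object@pollutant, object@receptor, nrow(object@values)))
})

setMethod("show", "HealthTables", function(object) {
  cat(sprintf(
    "HealthTables: %d PM2.5 outcomes, beta=%.5f /ppb, TMREL %g-%g ppb, %d countries\n",
    length(object@rrLookup), object@beta, object@tmrelLow, object@tmrelHigh,
    length(unique(object@demographics$country))))
})

setMethod("show", "QuadraticFit", function(object) {
  cat(sprintf("QuadraticFit (receptor %s): %d cells, ranks %s\n",
              object@receptor, length(object@cells),
              paste(sort(unique(object@rank)), collapse = "/")))
})
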