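#' Round half away from zero
#'
#' Matches how published tables print (23.64 % prints as 24 %), unlike
#' base round()'s round-half-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Load the G20 imported/domestic mortality table
#'
#' Reads the packaged country-level table of imported and domestic PM2.5-
#' and O3-related premature deaths (thousands) with the published RERER per
#' pollutant, and validates it: 43 records, and each printed RERER must be
#' attainable from its imported/domestic counts given their two-decimal
#' rounding (the published RERER column was computed from unrounded counts,
#' so exact recomputation from the rounded counts can differ in the last
#' digit; consistency is checked against the +/-0.005 input intervals).
#'
#' @param path CSV path (defaults to the packaged fixture)
#' @return data.frame with columns country, iso3, imported_pm25,
#'   imported_o3, domestic_pm25, domestic_o3, rerer_pm25, rerer_o3
#' @export
loadTable1 <- function(path = system.file("extdata", "table1_g20.csv",
                                          package = "srhia")) {
  t1 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "iso3", "imported_pm25", "imported_o3",
            "domestic_pm25", "domestic_o3", "rerer_pm25", "rerer_o3")
  if (!all(need %in% names(t1)))
    stop("fixture corruption: missing columns ",
         paste(setdiff(need, names(t1)), collapse = ", "))
  if (nrow(t1) != 43L)
    stop("fixture corruption: expected 43 records, found ", nrow(t1))
  if (anyDuplicated(t1$iso3)) stop("fixture corruption: duplicated ISO-3")
  for (p in c("pm25", "o3")) {
    ok <- rererConsistent(t1[[paste0("imported_", p)]],
                          t1[[paste0("domestic_", p)]],
                          t1[[paste0("rerer_", p)]])
    if (!all(ok))
      stop("fixture corruption: RERER inconsistent with death counts for ",
           paste(t1$iso3[!ok], collapse = ", "), " (", p, ")")
  }
  t1
}

#' Is a printed RERER consistent with rounded death counts?
#'
#' Checks that a RERER value printed to two decimals is attainable as
#' imported/(imported+domestic) for some unrounded counts within the
#' half-ULP (+/-0.005) rounding interval of the printed imported and
#' domestic values.
#'
#' @param imported,domestic printed counts (2 d.p., thousands)
#' @param printed printed RERER (2 d.p.)
#' @param ulp half-width of the input rounding interval
#' @return logical vector
#' @export
rererConsistent <- function(imported, domestic, printed, ulp = 0.005) {
  lo <- (imported - ulp) / ((imported - ulp) + (domestic + ulp))
  den <- (imported + ulp) + (domestic - ulp)
  hi <- ifelse(den > 0, (imported + ulp) / den, Inf)
  lo <= printed + ulp & hi >= printed - ulp
}

#' Printed aggregates of the mortality table
#'
#' Sums and unweighted means over the 43 countries for one pollutant:
#' total deaths (imported + domestic, thousands), imported and domestic
#' totals, the imported share (%), the unweighted mean of the printed
#' per-country RERER values, and the share of all domestic deaths
#' contributed by the three dominant domestic burdens (CHN, IND, USA).
#'
#' @param records table from \code{\link{loadTable1}}
#' @param pollutant "pm25" or "o3"
#' @param top ISO-3 codes of the top-domestic group
#' @return list(total, imported, domestic, importedShare, meanRerer,
#'   topDomesticShare); totals in thousands, shares in percent
#' @export
aggregateTable1 <- function(records, pollutant = c("pm25", "o3"),
                            top = c("CHN", "IND", "USA")) {
  pollutant <- match.arg(pollutant)
  imp <- records[[paste0("imported_", pollutant)]]
  dom <- records[[paste0("domestic_", pollutant)]]
  rr <- records[[paste0("rerer_", pollutant)]]
  inTop <- records$iso3 %in% top
  list(total = sum(imp) + sum(dom),
       imported = sum(imp),
       domestic = sum(dom),
       importedShare = 100 * sum(imp) / (sum(imp) + sum(dom)),
       meanRerer = mean(rr),
       topDomesticShare = 100 * sum(dom[inTop]) / sum(dom))
}

#' Rank countries by a table column
#'
#' Descending sort on the requested column; ties broken by ISO-3 code.
#'
#' @param records table from \code{\link{loadTable1}}
#' @param column a numeric column name, or "imported_total" /
#'   "domestic_total" for the PM2.5 + O3 sums
#' @return records reordered, with a `rank` column
#' @export
rankReceptors <- function(records, column = "imported_pm25") {
  vals <- switch(column,
    imported_total = records$imported_pm25 + records$imported_o3,
    domestic_total = records$domestic_pm25 + records$domestic_o3,
    {
      if (!column %in% names(records) || !is.numeric(records[[column]]))
        stop("unknown or non-numeric column: ", column)
      records[[column]]
    })
  ord <- order(-vals, records$iso3)
  out <- records[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
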