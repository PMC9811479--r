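#' PM2.5 outcomes with GBD-style look-up relative-risk curves
#' @export
PM25_OUTCOMES <- c("ihd", "stroke", "copd", "lri", "lung_cancer", "t2dm")

#' Generate synthetic GBD-style health tables
#'
#' Monotone, concave relative-risk look-up curves for the six PM2.5
#' outcomes (RR = 1 at zero exposure, saturating at outcome-specific
#' maxima); the O3-COPD log-linear slope beta = ln(1.06)/10 per ppb with a
#' uniform TMREL on 29.1-35.7 ppb; log-normal country populations with a
#' deterministic growth path; and baseline mortality rates y0 with
#' foresight-style 5-year rate increments 2015-2040 from which annual
#' projections are derived. All values are synthetic stand-ins with
#' realistic magnitudes, not GBD data.
#'
#' @param countries country codes
#' @param years years to cover in the demographics table (default
#'   2019:2040)
#' @param seed integer seed
#' @return a \linkS4class{HealthTables}
#' @export
buildHealthTables <- function(countries, years = 2019:2040, seed = 1L) {
  set.seed(seed)
  amax <- c(ihd = 0.9, stroke = 0.7, copd = 0.5, lri = 0.6,
            lung_cancer = 0.4, t2dm = 0.3)
  knots <- seq(0, 100, by = 5)
  rrLookup <- lapply(PM25_OUTCOMES, function(o) {
    a <- amax[[o]] * stats::runif(1, 0.85, 1.15)
    tau <- stats::runif(1, 25, 60)
    data.frame(exposure = knots, rr = 1 + a * (1 - exp(-knots / tau)))
  })
  names(rrLookup) <- PM25_OUTCOMES

  y0base <- c(ihd = 1.5e-3, stroke = 1.0e-3, copd = 6e-4, lri = 4e-4,
              lung_cancer = 3e-4, t2dm = 2e-4)
  demo <- expand.grid(country = countries, outcome = PM25_OUTCOMES,
                      stringsAsFactors = FALSE)
  demo$y0_2019 <- y0base[demo$outcome] * stats::rlnorm(nrow(demo), 0, 0.3)
  pop2019 <- stats::setNames(stats::rlnorm(length(countries), log(5e7), 0.8),
                             countries)
  growth <- stats::setNames(stats::runif(length(countries), 0.000, 0.013),
                            countries)
  trend <- stats::setNames(stats::runif(nrow(demo), 0.985, 1.02),
                           paste(demo$country, demo$outcome))

  incYears <- seq(2015, 2040, by = 5)
  foresight <- do.call(rbind, lapply(seq_len(nrow(demo)), function(i) {
    g <- trend[[paste(demo$country[i], demo$outcome[i])]]
    data.frame(country = demo$country[i], outcome = demo$outcome[i],
               year = incYears,
               rate = demo$y0_2019[i] * g^(incYears - 2019))
  }))

  proj <- projectMortalityRates(
    data.frame(country = demo$country, outcome = demo$outcome,
               y0 = demo$y0_2019), foresight)
  demographics <- merge(
    proj[proj$year %in% years, ],
    data.frame(country = rep(countries, each = length(years)),
               year = rep(years, times = length(countries)),
               pop = as.vector(vapply(countries, function(cn)
                 pop2019[[cn]] * (1 + growth[[cn]])^(years - 2019),
                 numeric(length(years))))),
    by = c("country", "year"))
  demographics <- demographics[order(demographics$country,
                                     demographics$outcome,
                                     demographics$year),
                               c("country", "outcome", "year", "pop", "y0")]
  rownames(demographics) <- NULL

  new("HealthTables", rrLookup = rrLookup, beta = log(1.06) / 10,
      tmrelLow = 29.1, tmrelHigh = 35.7, demographics = demographics,
      foresight = foresight)
}

#' PM2.5 relative risk by look-up interpolation
#'
#' Piecewise-linear interpolation between look-up knots; RR = 1 below the
#' first knot and held flat above the last.
#'
#' @param exposure exposure value(s), ug/m3
#' @param table data.frame(exposure, rr) with strictly increasing exposures
#' @return relative risk(s)
#' @export
pm25RelativeRisk <- function(exposure, table) {
  if (is(table, "HealthTables"))
    stop("pass one outcome's look-up table, e.g. tables@rrLookup$ihd")
  if (!NROW(table)) stop("configuration error: empty look-up table")
  rr <- stats::approx(table$exposure, table$rr, xout = exposure,
                      rule = 2)$y
  rr[exposure < table$exposure[1]] <- 1
  rr
}

#' O3 relative risk (log-linear with TMREL integration)
#'
#' RR = mean over n evenly spaced TMREL quantile midpoints of
#' exp(beta * max(0, exposure - TMREL_q)), integrating the uniform TMREL
#' distribution deterministically.
#'
#' @param exposure exposure value(s), ppb
#' @param beta log-RR slope per ppb
#' @param tmrelLow,tmrelHigh TMREL distribution bounds, ppb
#' @param nPoints number of quantile points (>= 1); 1 collapses the
#'   distribution to its lower bound (a degenerate TMREL at tmrelLow is
#'   obtained with tmrelHigh = tmrelLow + tiny and nPoints = 1)
#' @param tables optionally a \linkS4class{HealthTables}, supplying beta
#'   and the TMREL bounds
#' @return relative risk(s)
#' @export
o3RelativeRisk <- function(exposure, tables = NULL, beta = log(1.06) / 10,
                           tmrelLow = 29.1, tmrelHigh = 35.7, nPoints = 64L) {
  if (!is.null(tables)) {
    beta <- tables@beta; tmrelLow <- tables@tmrelLow; tmrelHigh <- tables@tmrelHigh
  }
  if (nPoints < 1L) stop("validation error: nPoints must be >= 1")
  if (beta <= 0) stop("validation error: beta must be positive")
  q <- tmrelLow + (seq_len(nPoints) - 0.5) / nPoints * (tmrelHigh - tmrelLow)
  vapply(exposure, function(x) mean(exp(beta * pmax(0, x - q))), numeric(1))
}

#' Attributable mortality
#'
#' Excess deaths associated with a relative-risk level:
#' y0 * (1 - 1/RR) * Pop. Signed for RR < 1 (a counterfactual exceeding
#' the baseline).
#'
#' @param rr relative risk (> 0)
#' @param y0 baseline mortality rate, deaths per person-year
#' @param pop exposed population, persons
#' @return deaths
#' @export
attributableMortality <- function(rr, y0, pop) {
  if (any(rr <= 0)) stop("validation error: RR must be positive")
  y0 * (1 - 1 / rr) * pop
}

#' Health impact of a source or scenario contribution
#'
#' Difference between the attributable burden at the baseline exposure and
#' at the counterfactual (baseline minus the contribution): PM2.5 sums the
#' six look-up outcomes, O3 uses COPD under the log-linear model. y0 and
#' population come from the tables' demographics for the given year.
#'
#' @param baseline,counterfactual country exposure values (ug/m3 or ppb)
#' @param tables a \linkS4class{HealthTables}
#' @param pollutant "PM25" or "O3"
#' @param country country code
#' @param year demographics year
#' @return deaths attributable to the contribution (baseline minus
#'   counterfactual burden)
#' @export
sourceHealthImpact <- function(baseline, counterfactual, tables, pollutant,
                               country, year = 2019) {
  if (counterfactual < 0) counterfactual <- 0
  d <- tables@demographics
  d <- d[d$country == country & d$year == year, ]
  if (!nrow(d)) stop("no demographics for ", country, " in ", year)
  if (pollutant == "PM25") {
    tot <- 0
    for (o in PM25_OUTCOMES) {
      row <- d[d$outcome == o, ]
      rrB <- pm25RelativeRisk(baseline, tables@rrLookup[[o]])
      rrC <- pm25RelativeRisk(counterfactual, tables@rrLookup[[o]])
      tot <- tot + attributableMortality(rrB, row$y0, row$pop) -
        attributableMortality(rrC, row$y0, row$pop)
    }
    tot
  } else {
    row <- d[d$outcome == "copd", ]
    rrB <- o3RelativeRisk(baseline, tables)
    rrC <- o3RelativeRisk(counterfactual, tables)
    attributableMortality(rrB, row$y0, row$pop) -
      attributableMortality(rrC, row$y0, row$pop)
  }
}

#' Project baseline mortality rates by annualized 5-year changes
#'
#' Computes the annualized percent change of foresight-style rates within
#' each 5-year increment, r = (rate_end/rate_start)^(1/5) - 1; applies the
#' 2015-2020 rate for one year to step the 2019 baseline to 2020, then
#' compounds each increment's annualized rate yearly through 2040.
#'
#' @param y0_2019 data.frame(country, outcome, y0) of 2019 baseline rates
#' @param foresight data.frame(country, outcome, year, rate) on 5-year
#'   increments 2015..2040
#' @return data.frame(country, outcome, year, y0) for 2019..2040
#' @export
projectMortalityRates <- function(y0_2019, foresight) {
  yrs <- sort(unique(foresight$year))
  if (!identical(yrs, seq(2015, 2040, by = 5)))
    stop("foresight rates must cover 2015-2040 in 5-year increments")
  if (any(foresight$rate <= 0))
    stop("validation error: nonpositive foresight rates")
  out <- lapply(seq_len(nrow(y0_2019)), function(i) {
    cn <- y0_2019$country[i]; o <- y0_2019$outcome[i]
    f <- foresight[foresight$country == cn & foresight$outcome == o, ]
    f <- f[order(f$year), ]
    ann <- (f$rate[-1] / f$rate[-nrow(f)])^(1 / 5) - 1
    names(ann) <- head(f$year, -1)
    y <- numeric(22); names(y) <- 2019:2040
    y[["2019"]] <- y0_2019$y0[i]
    y[["2020"]] <- y[["2019"]] * (1 + ann[["2015"]])
    for (t in 2021:2040) {
      inc <- as.character(2020 + 5 * ((t - 1 - 2020) %/% 5))
      y[[as.character(t)]] <- y[[as.character(t - 1)]] * (1 + ann[[inc]])
    }
    data.frame(country = cn, outcome = o, year = 2019:2040, y0 = unname(y))
  })
  do.call(rbind, out)
}

#' Rescale modelled exposures to a reference baseline
#'
#' Multiplies contributions by reference/modeled (times a configurable
#' daily-metric conversion factor, default 1), aligning modelled exposure
#' levels with an external baseline estimate. Linear, so it commutes with
#' aggregation.
#'
#' @param x contribution values (any numeric structure)
#' @param modeled modelled exposure (> 0)
#' @param reference reference exposure
#' @param metricFactor additional multiplicative conversion (e.g. a
#'   1-hour-max to 8-hour-max O3 metric factor)
#' @return list(factor, values)
#' @export
rescaleExposureToBaseline <- function(x, modeled, reference,
                                      metricFactor = 1) {
  if (modeled <= 0) stop("modeled exposure must be positive")
  f <- reference / modeled * metricFactor
  list(factor = f, values = x * f)
}
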