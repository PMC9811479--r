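kernelMatrix <- function(transfer, pollutant, receptor) {
  k <- transfer@kernels[[pollutant]]
  matrix(k[receptor, , ], dim(k)[2], dim(k)[3],
         dimnames = list(NULL, dimnames(k)[[3]]))
}

checkGridMatch <- function(transfer, E) {
  if (dim(transfer@kernels$PM25)[2] != dim(E)[1])
    stop("dimension error: emission field is not on the transfer model's grid")
}

#' Evaluate the surrogate cost function
#'
#' Closed-form exposure for one receptor and pollutant:
#' J = background + sum(kernel * E) + sum(gamma * E_NOx^2), the quadratic
#' term applying only to the O3 pathway. Exact; no stochasticity.
#'
#' @param transfer a \linkS4class{SurrogateTransfer}
#' @param E emission values array [cell, species, sector] (or an
#'   \linkS4class{EmissionField})
#' @param receptor receptor country code
#' @param pollutant "PM25" or "O3"
#' @return exposure value (ug/m3 for PM25, ppb for O3)
#' @export
surrogateCost <- function(transfer, E, receptor, pollutant = "PM25") {
  if (is(E, "EmissionField")) E <- E@values
  checkGridMatch(transfer, E)
  if (!receptor %in% transfer@receptors) stop("unknown receptor: ", receptor)
  k <- kernelMatrix(transfer, pollutant, receptor)
  j <- transfer@background[receptor, pollutant] +
    sum(k * apply(E, c(1, 2), sum))
  if (pollutant == "O3")
    j <- j + sum(transfer@gamma[receptor, ] * cellNOx(E)^2)
  j
}

#' Analytic adjoint-style sensitivity
#'
#' Gradient of the surrogate cost function with respect to per-cell,
#' per-species emissions at the supplied emission state: the linear kernel
#' for linear species, kernel + 2*gamma*E_NOx for NOx on the O3 pathway.
#'
#' @inheritParams surrogateCost
#' @return a \linkS4class{SensitivityField}
#' @export
surrogateSensitivity <- function(transfer, E, receptor, pollutant = "PM25") {
  if (is(E, "EmissionField")) E <- E@values
  checkGridMatch(transfer, E)
  if (!receptor %in% transfer@receptors) stop("unknown receptor: ", receptor)
  lam <- kernelMatrix(transfer, pollutant, receptor)
  if (pollutant == "O3")
    lam[, "NOx"] <- lam[, "NOx"] + 2 * transfer@gamma[receptor, ] * cellNOx(E)
  new("SensitivityField", values = lam, receptor = receptor,
      pollutant = pollutant)
}

#' Emission fields of the four forward-model states
#'
#' T: base; N: natural only (all anthropogenic sectors zeroed);
#' Z: anthropogenic NOx reduced to 10 %; D: anthropogenic NOx doubled.
#' Only the stated species/sectors are perturbed.
#'
#' @param E emission values array [cell, species, sector]
#' @return named list of arrays T, N, Z, D
#' @export
stateEmissions <- function(E) {
  if (is(E, "EmissionField")) E <- E@values
  EN <- E; EN[, , ANTHRO_SECTORS] <- 0
  EZ <- E; EZ[, "NOx", ANTHRO_SECTORS] <- 0.1 * EZ[, "NOx", ANTHRO_SECTORS]
  ED <- E; ED[, "NOx", ANTHRO_SECTORS] <- 2 * ED[, "NOx", ANTHRO_SECTORS]
  list(T = E, N = EN, Z = EZ, D = ED)
}

#' Run the four forward-model states through the surrogate
#'
#' Exact cost-function evaluations for every receptor and pollutant under
#' the base, natural-only, 10 % anthropogenic NOx and doubled anthropogenic
#' NOx states.
#'
#' @param transfer a \linkS4class{SurrogateTransfer}
#' @param E emission values array or \linkS4class{EmissionField}
#' @return a \linkS4class{ScenarioOutputs}
#' @export
surrogateScenarioRuns <- function(transfer, E) {
  if (is(E, "EmissionField")) E <- E@values
  checkGridMatch(transfer, E)
  states <- stateEmissions(E)
  rec <- transfer@receptors
  J <- array(NA_real_, dim = c(length(rec), length(POLLUTANTS), 4L),
             dimnames = list(rec, POLLUTANTS, c("T", "N", "Z", "D")))
  for (r in rec) for (p in POLLUTANTS) for (st in names(states))
    J[r, p, st] <- surrogateCost(transfer, states[[st]], r, p)
  new("ScenarioOutputs", J = J)
}
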