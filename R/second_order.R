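#' Design matrix of the per-cell quadratic O3-NOx fit
#'
#' Five rows: (E^2, E, 1) at the base (T), natural-only (N), 10 %
#' anthropogenic NOx (Z) and doubled anthropogenic NOx (D) emission values
#' of one cell, plus the derivative row (2*E_T, 1, 0) that ties the fit's
#' slope at the base state to the adjoint sensitivity.
#'
#' @param eT,eN,eZ,eD cell NOx emission value under each state (Tg/yr)
#' @return 5 x 3 matrix
#' @export
buildDesignMatrix <- function(eT, eN, eZ, eD) {
  e <- c(eT, eN, eZ, eD)
  if (any(!is.finite(e)) || any(e < 0))
    stop("validation error: state emissions must be finite and nonnegative")
  rbind(cbind(e^2, e, 1), c(2 * eT, 1, 0))
}

#' Data vector of the per-cell quadratic fit
#'
#' The first four elements are the cell's fractional share of each state's
#' cost-function value (first-order apportionment); the fifth is the
#' adjoint sensitivity, matched against the derivative row of the design
#' matrix.
#'
#' @param J numeric length-4, cost-function values for states T, N, Z, D
#' @param fractions numeric length-4, the cell's first-order fraction of
#'   each state's total contribution (0 for degenerate states)
#' @param lambda base-state sensitivity of the cost function to the cell's
#'   NOx emissions
#' @return numeric length-5
#' @export
buildDataVector <- function(J, fractions, lambda) {
  stopifnot(length(J) == 4L, length(fractions) == 4L, length(lambda) == 1L)
  c(fractions * J, lambda)
}

#' Rank-aware pseudoinverse least squares
#'
#' Solves G m = d through the Moore-Penrose pseudoinverse
#' m = V_p S_p^-1 U_p' d, where p is the numerical rank (singular values
#' above `tol` times the largest). Equals the normal-equations solution
#' whenever G has full column rank; stays finite on rank-deficient systems.
#'
#' @param G design matrix
#' @param d data vector
#' @param tol relative singular-value cutoff
#' @return list(coef, rank)
#' @export
pinvSolve <- function(G, d, tol = 1e-10) {
  if (any(!is.finite(G)) || any(!is.finite(d)))
    stop("G and d must be finite")
  sv <- svd(G)
  smax <- if (length(sv$d)) max(sv$d) else 0
  if (smax == 0) {
    warning("all-zero design matrix; returning zero coefficients")
    return(list(coef = numeric(ncol(G)), rank = 0L))
  }
  p <- sum(sv$d > tol * smax)
  coef <- sv$v[, seq_len(p), drop = FALSE] %*%
    ((1 / sv$d[seq_len(p)]) *
       (t(sv$u[, seq_len(p), drop = FALSE]) %*% d))
  list(coef = as.vector(coef), rank = as.integer(p))
}

#' First-order fractional apportionment of a state's cost function
#'
#' The fraction each (cell, NOx) source contributes to one state's total
#' first-order contribution over all cells and pollutant-relevant species.
#' Sensitivities are always the base-state ones; the emissions entering
#' numerator and denominator are the perturbed-state emissions by default
#' (`fractionEmissions = "base"` switches to base emissions throughout).
#'
#' @keywords internal
stateFractions <- function(lamBase, states, cells,
                           fractionEmissions = c("perturbed", "base")) {
  fractionEmissions <- match.arg(fractionEmissions)
  o3sp <- POLLUTANT_SPECIES$O3
  out <- matrix(0, length(cells), 4L,
                dimnames = list(NULL, c("T", "N", "Z", "D")))
  for (st in c("T", "N", "Z", "D")) {
    Est <- if (fractionEmissions == "base") states$T else states[[st]]
    denom <- sum(lamBase[, o3sp] * apply(Est[, o3sp, , drop = FALSE], c(1, 2), sum))
    num <- lamBase[cells, "NOx"] * rowSums(Est[cells, "NOx", , drop = FALSE])
    if (denom != 0) out[, st] <- num / denom
  }
  out
}

#' Fit per-cell quadratic O3-NOx response coefficients
#'
#' For one receptor, builds and solves the 5 x 3 least-squares system per
#' cell: four forward-model states apportioned to the cell by first-order
#' fractions plus the adjoint sensitivity as the derivative constraint,
#' solved by rank-aware pseudoinverse.
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param receptor receptor country code
#' @param cells grid cell indices to fit (default: all cells with
#'   anthropogenic NOx)
#' @param scenario precomputed \linkS4class{ScenarioOutputs} (optional)
#' @param fractionEmissions which emissions enter the state fractions; see
#'   details in the methods vignette
#' @param tol pseudoinverse rank tolerance
#' @return a \linkS4class{QuadraticFit}
#' @export
fitQuadratic <- function(world, receptor, cells = NULL,
                         scenario = NULL,
                         fractionEmissions = c("perturbed", "base"),
                         tol = 1e-10) {
  fractionEmissions <- match.arg(fractionEmissions)
  E <- emissionValues(world)
  if (is.null(cells))
    cells <- which(cellNOx(E, ANTHRO_SECTORS) > 0)
  if (is.null(scenario))
    scenario <- surrogateScenarioRuns(world@transfer, E)
  ## The fractions apportion emission-driven exposure, so the surrogate's
  ## additive background (a non-emission term with no analogue in a real
  ## chemical-transport cost function) is removed from the state values.
  J <- scenario@J[receptor, "O3", ] -
    world@transfer@background[receptor, "O3"]
  lamBase <- surrogateSensitivity(world@transfer, E, receptor, "O3")@values
  states <- stateEmissions(E)
  frac <- stateFractions(lamBase, states, cells, fractionEmissions)
  coef <- matrix(NA_real_, length(cells), 3L,
                 dimnames = list(NULL, c("c1", "c2", "c3")))
  rank <- integer(length(cells))
  for (i in seq_along(cells)) {
    cc <- cells[i]
    eStates <- vapply(states, function(Es) sum(Es[cc, "NOx", ]), numeric(1))
    G <- buildDesignMatrix(eStates[["T"]], eStates[["N"]],
                           eStates[["Z"]], eStates[["D"]])
    d <- buildDataVector(J, frac[i, ], lamBase[cc, "NOx"])
    fit <- pinvSolve(G, d, tol = tol)
    coef[i, ] <- fit$coef
    rank[i] <- fit$rank
  }
  new("QuadraticFit", coef = coef, rank = rank, cells = as.integer(cells),
      receptor = receptor)
}

#' Second-order (quadratic) contribution
#'
#' Anthropogenic contribution of a cell's NOx at emission level E under the
#' fitted quadratic: (c1 E^2 + c2 E + c3) - c3 = c1 E^2 + c2 E. The
#' intercept c3 (the fit's value at zero emissions) is subtracted so that
#' natural/background exposure is not attributed to anthropogenic NOx. With
#' c1 = 0 this reduces to the first-order form c2 * E.
#'
#' @param m coefficient vector (c1, c2, c3) or a \linkS4class{QuadraticFit}
#' @param E emission value(s); rows of a QuadraticFit pair with entries of E
#' @return exposure contribution(s)
#' @export
secondOrderContribution <- function(m, E) {
  if (is(m, "QuadraticFit")) {
    stopifnot(length(E) == nrow(m@coef))
    return(unname(m@coef[, "c1"] * E^2 + m@coef[, "c2"] * E))
  }
  unname(m[1] * E^2 + m[2] * E)
}

#' Split a cell-level quadratic contribution across sectors
#'
#' Proportional to each anthropogenic sector's share of the cell's
#' anthropogenic NOx.
#'
#' @param contribution cell-level contribution value
#' @param E emission values array [cell, species, sector]
#' @param cell grid cell index
#' @return named vector over anthropogenic sectors
#' @export
sectorSplit <- function(contribution, E, cell) {
  if (is(E, "EmissionField")) E <- E@values
  shares <- E[cell, "NOx", ANTHRO_SECTORS]
  tot <- sum(shares)
  if (tot == 0) return(stats::setNames(rep(0, length(ANTHRO_SECTORS)),
                                       ANTHRO_SECTORS))
  contribution * shares / tot
}
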