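#' Finite-difference perturbation test for one cell
#'
#' Perturbs a cell's anthropogenic NOx by the given fraction, records the
#' true exposure response of every O3 receptor by actually re-evaluating
#' the surrogate, and the first- and second-order adjoint projections of
#' the same perturbation. The receptor with the largest |true| response is
#' flagged (ties broken by receptor code order).
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param cell grid cell index with nonzero anthropogenic NOx
#' @param fraction perturbation fraction (e.g. 0.5 for +50 %)
#' @param fits optional named list of \linkS4class{QuadraticFit} per
#'   receptor covering `cell` (fitted on demand otherwise)
#' @return data.frame (cell, fraction, receptor, true, projFirst,
#'   projSecond, strongest)
#' @export
runPerturbationTest <- function(world, cell, fraction, fits = NULL) {
  E <- emissionValues(world)
  eAnth <- sum(E[cell, "NOx", ANTHRO_SECTORS])
  if (eAnth == 0) {
    warning("skipping cell ", cell, ": no anthropogenic NOx")
    return(NULL)
  }
  Ep <- E
  Ep[cell, "NOx", ANTHRO_SECTORS] <- (1 + fraction) * Ep[cell, "NOx", ANTHRO_SECTORS]
  dEcell <- fraction * eAnth
  eBase <- sum(E[cell, "NOx", ])
  ePert <- eBase + dEcell
  rec <- receptors(world)
  rows <- lapply(rec, function(r) {
    true <- surrogateCost(world@transfer, Ep, r, "O3") -
      surrogateCost(world@transfer, E, r, "O3")
    lam <- surrogateSensitivity(world@transfer, E, r, "O3")@values[cell, "NOx"]
    fit <- if (!is.null(fits)) fits[[r]] else
      fitQuadratic(world, r, cells = cell)
    i <- match(cell, fit@cells)
    m <- fit@coef[i, ]
    proj2 <- secondOrderContribution(m, ePert) -
      secondOrderContribution(m, eBase)
    data.frame(cell = cell, fraction = fraction, receptor = r, true = true,
               projFirst = lam * dEcell, projSecond = proj2)
  })
  out <- do.call(rbind, rows)
  best <- order(-abs(out$true), out$receptor)[1]
  out$strongest <- seq_len(nrow(out)) == best
  out
}

#' Score perturbation tests by normalized mean bias and R-squared
#'
#' NMB = 100 * sum(proj - true) / sum(|true|) over the strongest-response
#' receptor of each test; R-squared is the squared correlation of projected
#' versus true responses.
#'
#' @param tests data.frame from \code{\link{runPerturbationTest}} rows
#'   (strongest-receptor rows are used)
#' @param method "first" or "second"
#' @return list(nmb, r2, n)
#' @export
scoreTests <- function(tests, method = c("first", "second")) {
  method <- match.arg(method)
  t <- tests[tests$strongest, ]
  if (nrow(t) < 2L) stop("need at least two tests to score")
  if (all(t$true == 0)) stop("undefined score: all true responses are zero")
  proj <- if (method == "first") t$projFirst else t$projSecond
  list(nmb = 100 * sum(proj - t$true) / sum(abs(t$true)),
       r2 = stats::cor(proj, t$true)^2,
       n = nrow(t))
}

#' Run the full perturbation-test suite
#'
#' Samples the highest anthropogenic-NOx cells (21 by default), perturbs
#' each by +/- the given fraction, and scores first- versus second-order
#' projections in each direction.
#'
#' @param world a \linkS4class{SyntheticWorld}
#' @param nCellsTested number of cells (highest anthropogenic NOx first)
#' @param fraction perturbation magnitude (default 0.5)
#' @return list(tests, scores) where scores is a data.frame over
#'   (direction, method)
#' @export
evaluateProjections <- function(world, nCellsTested = 21L, fraction = 0.5) {
  E <- emissionValues(world)
  nox <- cellNOx(E, ANTHRO_SECTORS)
  cells <- order(-nox)[seq_len(min(nCellsTested, sum(nox > 0)))]
  fits <- lapply(receptors(world), function(r)
    fitQuadratic(world, r, cells = cells))
  names(fits) <- receptors(world)
  tests <- do.call(rbind, lapply(c(fraction, -fraction), function(f)
    do.call(rbind, lapply(cells, function(cc)
      runPerturbationTest(world, cc, f, fits = fits)))))
  scores <- do.call(rbind, lapply(c(fraction, -fraction), function(f) {
    sub <- tests[tests$fraction == f, ]
    do.call(rbind, lapply(c("first", "second"), function(m) {
      s <- scoreTests(sub, m)
      data.frame(fraction = f, method = m, nmb = s$nmb, r2 = s$r2, n = s$n)
    }))
  }))
  list(tests = tests, scores = scores)
}
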