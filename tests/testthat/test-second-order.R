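test_that("design matrix holds state emission powers plus the derivative row", {
  G <- buildDesignMatrix(1, 0, 0.1, 2)
  expect_equal(unname(G),
               rbind(c(1, 1, 1), c(0, 0, 1), c(0.01, 0.1, 1), c(4, 2, 1),
                     c(2, 1, 0)))
  expect_error(buildDesignMatrix(-1, 0, 0.1, 2), "nonnegative")
  # all-zero states leave only the intercept and slope columns
  expect_equal(qr(buildDesignMatrix(0, 0, 0, 0))$rank, 2)
})

test_that("rank is 3 whenever the states take at least three distinct values", {
  vals <- seq(0, 2, by = 0.5)
  for (eT in vals) for (eN in vals) for (eZ in vals) for (eD in vals) {
    G <- buildDesignMatrix(eT, eN, eZ, eD)
    nd <- length(unique(c(eT, eN, eZ, eD)))
    if (nd >= 3) expect_equal(qr(G)$rank, 3)
  }
})

test_that("data vector combines fractional state costs with the sensitivity", {
  expect_equal(buildDataVector(c(4, 0, 1, 8), rep(1, 4), 2.5),
               c(4, 0, 1, 8, 2.5))
  expect_equal(buildDataVector(c(4, 0, 1, 8), c(0.5, 0, 0.25, 0.5), 2.5),
               c(2, 0, 0.25, 4, 2.5))
})

test_that("pseudoinverse solves identity-padded and exactly consistent systems", {
  G <- rbind(diag(3), 0, 0)
  fit <- pinvSolve(G, c(7, -2, 3, 0, 0))
  expect_equal(fit$coef, c(7, -2, 3))
  expect_equal(fit$rank, 3L)
  # d generated exactly from m* = (1, 2, 3) at states E = (1, 0, 0.1, 2)
  G2 <- buildDesignMatrix(1, 0, 0.1, 2)
  mstar <- c(1, 2, 3)
  fit2 <- pinvSolve(G2, as.vector(G2 %*% mstar))
  expect_equal(fit2$coef, mstar, tolerance = 1e-10)
})

test_that("pseudoinverse agrees with normal equations on random full-rank systems", {
  set.seed(11)
  for (i in 1:100) {
    G <- matrix(rnorm(15), 5, 3)
    d <- rnorm(5)
    m1 <- pinvSolve(G, d)$coef
    m2 <- as.vector(solve(crossprod(G), crossprod(G, d)))
    expect_equal(m1, m2, tolerance = 1e-8)
    m3 <- as.vector(MASS::ginv(G) %*% d)
    expect_equal(m1, m3, tolerance = 1e-8)
  }
})

test_that("an all-zero system warns and returns a zero solution with rank 0", {
  expect_warning(fit <- pinvSolve(matrix(0, 5, 3), rep(0, 5)), "all-zero")
  expect_equal(fit$coef, c(0, 0, 0))
  expect_equal(fit$rank, 0L)
  expect_error(pinvSolve(matrix(NA_real_, 5, 3), rep(0, 5)), "finite")
})

test_that("fitted coefficients recover the exact per-cell quadratic truth", {
  # single cell, purely quadratic response, state fractions exactly 1
  w <- makeQuadraticWorld(k = 1.5, gamma = 0.3, eAnth = 1, eNat = 0.2)
  fit <- fitQuadratic(w, "AAA", cells = 1L)
  expect_equal(unname(fit@coef[1, ]), c(0.3, 1.5, 0), tolerance = 1e-8)
  expect_equal(fit@rank, 3L)
  # several identical cells: fractions 1/n, still exact
  w2 <- makeQuadraticWorld(k = rep(2, 4), gamma = rep(-0.05, 4),
                           eAnth = rep(0.8, 4), eNat = rep(0.1, 4))
  fit2 <- fitQuadratic(w2, "AAA")
  for (i in 1:4)
    expect_equal(unname(fit2@coef[i, ]), c(-0.05, 2, 0), tolerance = 1e-8)
  # concave and convex cells both recovered across random exact worlds
  set.seed(21)
  for (i in 1:10) {
    k <- runif(1, 0.5, 3); g <- runif(1, -0.1, 0.4); e <- runif(1, 0.2, 2)
    wi <- makeQuadraticWorld(k = k, gamma = g, eAnth = e, eNat = runif(1, 0, 0.3))
    fi <- fitQuadratic(wi, "AAA", cells = 1L)
    expect_equal(unname(fi@coef[1, ]), c(g, k, 0), tolerance = 1e-8)
  }
})

test_that("the consistency oracle: exact-quadratic single-cell d leaves no fit residual", {
  w <- makeQuadraticWorld(k = 1.2, gamma = 0.25, eAnth = 1.5, eNat = 0.3)
  fit <- fitQuadratic(w, "AAA", cells = 1L)
  states <- stateEmissions(emissionValues(w))
  eS <- vapply(states, function(Es) sum(Es[1, "NOx", ]), numeric(1))
  G <- buildDesignMatrix(eS[["T"]], eS[["N"]], eS[["Z"]], eS[["D"]])
  sc <- surrogateScenarioRuns(w@transfer, w@emissions)
  lam <- surrogateSensitivity(w@transfer, w@emissions, "AAA", "O3")@values[1, "NOx"]
  d <- buildDataVector(sc@J["AAA", "O3", ], rep(1, 4), lam)
  expect_lt(max(abs(G %*% cbind(fit@coef[1, ]) - d)), 1e-10)
})

test_that("second-order contribution has a linear limit and passes the zero-out oracle", {
  expect_equal(secondOrderContribution(c(0.5, 2, 7), 0), 0)
  expect_equal(secondOrderContribution(c(0, 2, 7), 3), 6)  # c1 = 0: first-order form
  w <- makeQuadraticWorld(k = 1.5, gamma = 0.3, eAnth = 1, eNat = 0.2)
  fit <- fitQuadratic(w, "AAA", cells = 1L)
  eT <- sum(emissionValues(w)[1, "NOx", ])
  contrib <- secondOrderContribution(fit, eT)
  E0 <- emissionValues(w); E0[1, "NOx", ] <- 0
  truth <- surrogateCost(w@transfer, w@emissions, "AAA", "O3") -
    surrogateCost(w@transfer, E0, "AAA", "O3")
  expect_equal(contrib, truth, tolerance = 1e-8)
})

test_that("with zero curvature second-order equals first-order attribution", {
  w <- makeQuadraticWorld(k = c(1, 2, 0.5), gamma = c(0, 0, 0),
                          eAnth = c(1, 0.3, 2), eNat = c(0.2, 0, 0.1))
  fit <- fitQuadratic(w, "AAA")
  E <- emissionValues(w)
  eTot <- rowSums(E[, "NOx", ])
  lam <- surrogateSensitivity(w@transfer, E, "AAA", "O3")@values[, "NOx"]
  expect_equal(secondOrderContribution(fit, eTot[fit@cells]),
               (lam * eTot)[fit@cells], tolerance = 1e-10)
})

test_that("cell-level quadratic contributions split across sectors by NOx share", {
  w <- sharedWorld()
  E <- emissionValues(w)
  cc <- which(rowSums(E[, "NOx", ANTHRO_SECTORS]) > 0)[1]
  split <- sectorSplit(10, E, cc)
  expect_equal(sum(split), 10, tolerance = 1e-12)
  shares <- E[cc, "NOx", ANTHRO_SECTORS] / sum(E[cc, "NOx", ANTHRO_SECTORS])
  expect_equal(split, 10 * shares, tolerance = 1e-12)
  Ez <- E; Ez[2, "NOx", ANTHRO_SECTORS] <- 0
  expect_equal(sum(sectorSplit(10, Ez, 2)), 0)
})
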