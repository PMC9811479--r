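# Hand-built miniature worlds with fully known transfer coefficients, so
# tests can compare against closed forms independent of buildWorld().

# A world of `n` cells in one country whose O3 response is exactly
# quadratic in NOx: J_O3 = sum(k * E_NOx) + sum(gamma * E_NOx_tot^2).
# Only NOx has a nonzero O3 kernel, so single-cell worlds have state
# fractions of exactly 1.
makeQuadraticWorld <- function(k, gamma, eAnth, eNat = 0, background = 0,
                               code = "AAA") {
  n <- length(k)
  stopifnot(length(gamma) == n, length(eAnth) == n)
  eNat <- rep_len(eNat, n)
  grid <- new("WorldGrid", latEdges = seq(0, 10, length.out = n + 1L),
              lonEdges = c(0, 10))
  mask <- new("RegionMask", assignment = rep(code, n), countries = code)
  E <- array(0, dim = c(n, length(SPECIES), length(SECTORS)),
             dimnames = list(NULL, SPECIES, SECTORS))
  E[, "NOx", "TRN"] <- eAnth
  E[, "NOx", "NAT"] <- eNat
  kern <- array(0, dim = c(1L, n, length(SPECIES)),
                dimnames = list(code, NULL, SPECIES))
  kern[1, , "NOx"] <- k
  kernPM <- array(0, dim = c(1L, n, length(SPECIES)),
                  dimnames = list(code, NULL, SPECIES))
  kernPM[1, , "BC"] <- 1
  transfer <- new("SurrogateTransfer",
                  kernels = list(PM25 = kernPM, O3 = kern),
                  gamma = matrix(gamma, 1L, n, dimnames = list(code, NULL)),
                  background = matrix(background, 1L, 2L,
                                      dimnames = list(code, POLLUTANTS)),
                  receptors = code)
  new("SyntheticWorld", grid = grid, mask = mask,
      population = rep(1, n), emissions = new("EmissionField", values = E),
      transfer = transfer, seed = 0L)
}

# Small seeded default world shared across tests (built once per run).
sharedWorld <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- buildWorld(seed = 42L)
    w
  }
})

sharedLinearWorld <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- buildWorld(seed = 42L, curved = FALSE)
    w
  }
})
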