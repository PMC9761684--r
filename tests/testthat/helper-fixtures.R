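# All fixtures are built in code.

# minimal bundle with identity-like normal modes and zero Coriolis
mkBundle <- function(omega, cubic = NULL, quartic = NULL, props = list(),
                     zeta = NULL, Beq = c(1, 1, 1)) {
  n <- length(omega)
  nAtoms <- max(3L, as.integer(ceiling((n + 6) / 3)))
  L <- diag(1, 3 * nAtoms)[, seq_len(n), drop = FALSE]
  if (is.null(zeta)) zeta <- array(0, c(3, n, n))
  harm <- new("HarmonicModel", nAtoms = nAtoms, linear = FALSE,
              omega = omega, L = L, Beq = Beq, zeta = zeta,
              geometry = matrix(0, nAtoms, 3))
  field <- anharmonicField(n, cubic = cubic, quartic = quartic)
  new("VibData", harmonic = harm, field = field, properties = props)
}

cubicDf <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(i = m[, 1], j = m[, 2], k = m[, 3], value = m[, 4])
}

quarticDf <- function(...) {
  m <- matrix(c(...), ncol = 5, byrow = TRUE)
  data.frame(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4], value = m[, 5])
}

scalarSurface <- function(n, P0 = 0, P1 = NULL, P2 = NULL, P3 = list(),
                          S = 1, name = "electric_dipole") {
  if (is.null(P1)) P1 <- matrix(0, n, 1)
  if (is.null(P2)) P2 <- array(0, c(n, n, 1))
  new("PropertySurface", name = name, nComponents = 1L, S = S,
      s0 = 1, s1 = 1, s2 = 1, s3 = 1, P0 = P0,
      P1 = matrix(P1, n, 1), P2 = array(P2, c(n, n, 1)), P3 = P3,
      units = "au")
}

# strong type-I Fermi dyad from the methyloxirane neat-liquid conditions:
# gap 2.6 cm-1, cubic coupling 38 cm-1
fermiDyadBundle <- function(delta = 2.6, phi = 38) {
  mkBundle(c(800, 1600 + delta),
           cubic = cubicDf(1, 1, 2, phi),
           quartic = quarticDf(1, 1, 1, 1, 5, 2, 2, 2, 2, 5))
}
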