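## Synthetic vibrational systems with planted resonances, plus the dense
## variational oracle that serves as the package's ground truth on small
## mode counts. The generator's defaults emulate the fingerprint region of
## a mid-size organic molecule: wavenumbers uniform on 300-1700 cm-1 with a
## minimum spacing, sparse zero-mean cubic constants of ~10 cm-1 scale,
## diagonal quartics of comparable size, and dipole-type property surfaces
## of ~0.05 au first derivatives.

#' Plan for a synthetic bundle with planted resonances
#'
#' @param nModes number of modes.
#' @param planted list of features, each
#'   \code{list(kind = "FERMI_I"|"FERMI_II"|"DD11", delta =, coupling =)}:
#'   the harmonic gap (cm-1) is realized exactly in the generated
#'   wavenumbers and the coupling constant (cm-1) planted in the force
#'   field (cubic constant for Fermi; quartic K_iijj for DD11).
#' @param omegaRange range of background wavenumbers, cm-1.
#' @param minSpacing minimum spacing enforced between background
#'   wavenumbers, cm-1 (avoids accidental degeneracies).
#' @param cubicScale sd of background cubic constants, cm-1.
#' @param quarticScale sd of background semidiagonal quartics, cm-1.
#' @param backgroundDensity fraction of semidiagonal constants that are
#'   nonzero in the background field.
#' @param propertyScale sd of dipole first derivatives, au.
#' @param seed RNG seed; generation is reproducible for a fixed seed.
#' @return a plan object (list).
#' @export
resonancePlan <- function(nModes, planted = list(),
                          omegaRange = c(300, 1700), minSpacing = 8,
                          cubicScale = 10, quarticScale = 5,
                          backgroundDensity = 0.15,
                          propertyScale = 0.05, seed = 1L) {
  need <- sum(vapply(planted, function(p)
    switch(p$kind, FERMI_I = 2L, FERMI_II = 3L, DD11 = 2L,
           stop("unknown planted kind ", p$kind)), integer(1)))
  if (need > nModes)
    stop("infeasible plan: planted features need more modes than available")
  list(nModes = as.integer(nModes), planted = planted,
       omegaRange = omegaRange, minSpacing = minSpacing,
       cubicScale = cubicScale, quarticScale = quarticScale,
       backgroundDensity = backgroundDensity,
       propertyScale = propertyScale, seed = as.integer(seed))
}

#' Generate a synthetic VibData bundle from a plan
#'
#' Planted gaps are achieved exactly; the manifest records which final mode
#' indices realize each feature. Coriolis couplings are zero so the bundle
#' can double as an oracle fixture (the Hamiltonian stays polynomial).
#'
#' @param plan from \code{\link{resonancePlan}}.
#' @return list(bundle = \code{VibData}, manifest = data.frame of planted
#'   features with realized mode indices).
#' @export
generateBundle <- function(plan) {
  set.seed(plan$seed)
  n <- plan$nModes
  sampleSpaced <- function(k, range, spacing) {
    if (k == 0L) return(numeric(0))
    for (try in 1:200) {
      x <- sort(stats::runif(k, range[1], range[2]))
      if (k < 2 || min(diff(x)) >= spacing) return(x)
    }
    stop("could not satisfy the minimum wavenumber spacing")
  }
  need <- vapply(plan$planted, function(p)
    switch(p$kind, FERMI_I = 2L, FERMI_II = 3L, DD11 = 2L), integer(1))
  nBase <- n - sum(vapply(plan$planted, function(p)
    switch(p$kind, FERMI_I = 1L, FERMI_II = 1L, DD11 = 1L), integer(1)))
  base <- sampleSpaced(nBase, plan$omegaRange, plan$minSpacing)
  omega <- base
  anchors <- list()
  used <- integer(0)
  pickAnchor <- function(k, upper = Inf) {
    avail <- setdiff(which(base < upper), used)
    if (length(avail) < k) avail <- setdiff(seq_along(base), used)
    if (length(avail) < k) stop("infeasible plan: not enough anchor modes")
    picked <- avail[seq_len(k)]
    used <<- c(used, picked)
    picked
  }
  extra <- numeric(0)
  for (p in plan$planted) {
    if (p$kind == "FERMI_I") {
      a <- pickAnchor(1L, upper = plan$omegaRange[2] / 2 + 100)
      w <- 2 * base[a] + p$delta
      anchors[[length(anchors) + 1L]] <- list(p = p, donors = base[a], w = w)
    } else if (p$kind == "FERMI_II") {
      a <- pickAnchor(2L, upper = plan$omegaRange[2] / 2 + 100)
      w <- base[a[1]] + base[a[2]] + p$delta
      anchors[[length(anchors) + 1L]] <- list(p = p, donors = base[a], w = w)
    } else {
      a <- pickAnchor(1L)
      w <- base[a] - p$delta
      anchors[[length(anchors) + 1L]] <- list(p = p, donors = base[a], w = w)
    }
    extra <- c(extra, anchors[[length(anchors)]]$w)
  }
  omega <- sort(c(base, extra))
  findMode <- function(w) {
    i <- which.min(abs(omega - w))
    if (abs(omega[i] - w) > 1e-9) stop("internal: planted wavenumber lost")
    i
  }
  ## background force field
  cubRows <- list(); quaRows <- list()
  addCub <- function(i, j, k, v)
    cubRows[[length(cubRows) + 1L]] <<- data.frame(i = i, j = j, k = k, value = v)
  addQua <- function(i, j, k, l, v)
    quaRows[[length(quaRows) + 1L]] <<- data.frame(i = i, j = j, k = k, l = l, value = v)
  for (i in seq_len(n)) {
    addQua(i, i, i, i, stats::rnorm(1, 0, plan$quarticScale))
    for (j in seq_len(n)) {
      if (stats::runif(1) < plan$backgroundDensity)
        addCub(min(i, j), min(i, j), max(i, j),
               stats::rnorm(1, 0, plan$cubicScale))
    }
  }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < plan$backgroundDensity)
      addQua(i, i, j, j, stats::rnorm(1, 0, plan$quarticScale))
  if (n > 2) {
    nTriples <- max(1L, as.integer(plan$backgroundDensity * n))
    for (t_ in seq_len(nTriples)) {
      tri <- sort(sample(n, 3L))
      addCub(tri[1], tri[2], tri[3], stats::rnorm(1, 0, plan$cubicScale))
    }
  }
  ## planted couplings (override background)
  manifest <- list()
  for (an in anchors) {
    p <- an$p
    if (p$kind == "FERMI_I") {
      i <- findMode(an$w); j <- findMode(an$donors[1])
      addCub(min(i, j, j), sort(c(i, j, j))[2], max(i, j, j), 0) # clear slot
      addCub(j, j, i, p$coupling)
      manifest[[length(manifest) + 1L]] <-
        data.frame(kind = p$kind, i = i, j = j, k = j,
                   delta = p$delta, coupling = p$coupling)
    } else if (p$kind == "FERMI_II") {
      i <- findMode(an$w); j <- findMode(an$donors[1]); k <- findMode(an$donors[2])
      addCub(i, j, k, p$coupling)
      manifest[[length(manifest) + 1L]] <-
        data.frame(kind = p$kind, i = i, j = min(j, k), k = max(j, k),
                   delta = p$delta, coupling = p$coupling)
    } else {
      i <- findMode(an$donors[1]); j <- findMode(an$w)
      a <- min(i, j); b <- max(i, j)
      ## the direct quartic term <1_a|V4|1_b> = sum_k K_abkk / 8; the
      ## planted coupling is realized through the K_aaab pattern
      addQua(a, a, a, b, 8 * p$coupling)
      manifest[[length(manifest) + 1L]] <-
        data.frame(kind = p$kind, i = a, j = b, k = NA_integer_,
                   delta = if (i < j) p$delta else -p$delta,
                   coupling = p$coupling)
    }
  }
  cub <- do.call(rbind, cubRows)
  ## keep the last value written for each canonical key (planted overrides)
  keys <- apply(cub[, 1:3], 1, ffKey)
  cub <- cub[!duplicated(keys, fromLast = TRUE), , drop = FALSE]
  qua <- do.call(rbind, quaRows)
  keys <- apply(qua[, 1:4], 1, ffKey)
  qua <- qua[!duplicated(keys, fromLast = TRUE), , drop = FALSE]
  field <- anharmonicField(n, cubic = cub, quartic = qua)
  ## harmonic model: enough atoms to host n modes
  nAtoms <- max(3L, as.integer(ceiling((n + 6) / 3)))
  nCart <- 3L * nAtoms
  Lfull <- qr.Q(qr(matrix(stats::rnorm(nCart * nCart), nCart)))
  L <- Lfull[, seq_len(n), drop = FALSE]
  for (c_ in seq_len(n)) if (L[which.max(abs(L[, c_])), c_] < 0)
    L[, c_] <- -L[, c_]
  harm <- new("HarmonicModel", nAtoms = nAtoms, linear = FALSE,
              omega = omega, L = L,
              Beq = stats::runif(3, 0.1, 2),
              zeta = array(0, c(3L, n, n)),
              geometry = matrix(stats::rnorm(nAtoms * 3), nAtoms, 3L))
  mkSurface <- function(name, S, scale) {
    P2 <- array(stats::rnorm(n * n, 0, scale / 10), c(n, n, 3L))
    if (S == 1) for (c_ in 1:3) P2[, , c_] <- (P2[, , c_] + t(P2[, , c_])) / 2
    P3 <- list()
    for (i in seq_len(n)) {
      key <- paste(sort(c(i, i, sample(n, 1))), collapse = ".")
      if (S == -1) key <- paste(c(i, i, sample(n, 1)), collapse = ".")
      P3[[key]] <- stats::rnorm(3, 0, scale / 50)
    }
    new("PropertySurface", name = name, nComponents = 3L, S = S,
        s0 = 1, s1 = 1, s2 = 1, s3 = 1,
        P0 = stats::rnorm(3, 0, scale * 5),
        P1 = matrix(stats::rnorm(n * 3, 0, scale), n, 3L),
        P2 = P2, P3 = P3, units = "au")
  }
  props <- list(electric_dipole = mkSurface("electric_dipole", 1, plan$propertyScale),
                magnetic_dipole = mkSurface("magnetic_dipole", -1,
                                            plan$propertyScale / 5))
  bundle <- new("VibData", harmonic = harm, field = field, properties = props)
  validObject(bundle@harmonic); validObject(bundle@field); validObject(bundle)
  list(bundle = bundle,
       manifest = if (length(manifest)) do.call(rbind, manifest) else
         data.frame(kind = character(0), i = integer(0), j = integer(0),
                    k = integer(0), delta = numeric(0), coupling = numeric(0)))
}
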