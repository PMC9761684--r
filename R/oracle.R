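## Brute-force variational reference for small systems: dense
## diagonalization of the vibrational Hamiltonian (potential truncated at
## quartic, the same polynomial the perturbative machinery sees) in a
## harmonic-oscillator product basis, with transition moments evaluated
## between the numerical eigenvectors using the identically truncated
## property operator. Discrepancies between the oracle and VPT2 therefore
## measure perturbation error only.

#' Dense variational oracle for small bundles
#'
#' @param bundle a \code{VibData} with at most 3 modes and zero Coriolis
#'   couplings (the operator must stay polynomial).
#' @param nmax maximum quanta per mode in the product basis (<= 20).
#' @param lambda optional scaling of the perturbation: cubic terms are
#'   scaled by \code{lambda}, quartic by \code{lambda^2} (for
#'   perturbation-limit checks).
#' @param convergenceCheck re-diagonalize with nmax - 2 and error if the
#'   ground-state energy moves by more than 0.01 cm-1.
#' @return list with \code{values} (eigenvalues relative to the variational
#'   ground state), \code{vectors}, \code{basis} (matrix of quanta),
#'   \code{ground} (absolute ground energy), and the inputs needed by
#'   \code{\link{oracleEnergy}} / \code{\link{oracleMoment}}.
#' @export
variationalOracle <- function(bundle, nmax = 10L, lambda = 1,
                              convergenceCheck = TRUE) {
  harm <- bundle@harmonic
  n <- length(harm@omega)
  if (n > 3L) stop("oracle supports at most 3 modes")
  if (nmax > 20L) stop("nmax capped at 20 quanta per mode")
  if (max(abs(harm@zeta)) > 0)
    stop("oracle requires zeta = 0 (polynomial operator)")
  solve1 <- function(nm) {
    grid <- do.call(expand.grid, rep(list(0:nm), n))
    basis <- as.matrix(grid)[, n:1, drop = FALSE] # lexicographic by mode 1
    dim_ <- nrow(basis)
    keys <- apply(basis, 1, stateKeyV)
    v3t <- cubicTerms(bundle@field)
    v4t <- quarticTerms(bundle@field)
    if (lambda != 1) {
      v3t <- lapply(v3t, function(t) { t$coef <- t$coef * lambda; t })
      v4t <- lapply(v4t, function(t) { t$coef <- t$coef * lambda^2; t })
    }
    H <- diag(as.numeric(basis %*% harm@omega) + sum(harm@omega) / 2)
    for (col in seq_len(dim_)) {
      wf <- applyTerms(basis[col, ], c(v3t, v4t), nmax = nm)
      hit <- match(names(wf), keys)
      ok <- !is.na(hit)
      H[hit[ok], col] <- H[hit[ok], col] + unname(wf[ok])
    }
    H <- (H + t(H)) / 2
    eig <- eigen(H, symmetric = TRUE)
    o <- order(eig$values)
    vec <- eig$vectors[, o, drop = FALSE]
    for (c_ in seq_len(ncol(vec))) {
      m <- which.max(abs(vec[, c_]))
      if (vec[m, c_] < 0) vec[, c_] <- -vec[, c_]
    }
    list(values = eig$values[o], vectors = vec, basis = basis, keys = keys)
  }
  sol <- solve1(nmax)
  if (convergenceCheck && nmax > 3L) {
    ref <- solve1(nmax - 2L)
    if (abs(sol$values[1] - ref$values[1]) > 0.01)
      stop(sprintf("oracle basis not converged: ground state moved %.4f cm-1",
                   abs(sol$values[1] - ref$values[1])))
  }
  list(values = sol$values - sol$values[1], vectors = sol$vectors,
       basis = sol$basis, keys = sol$keys, ground = sol$values[1],
       bundle = bundle, nmax = nmax, lambda = lambda)
}

## index of the oracle eigenstate dominated by a given harmonic basis state
oracleLevelIndex <- function(oracle, state) {
  n <- ncol(oracle$basis)
  key <- stateKeyV(denseQuanta(state, n))
  row <- match(key, oracle$keys)
  if (is.na(row)) stop("state outside oracle basis")
  which.max(oracle$vectors[row, ]^2)
}

#' Oracle energy of the eigenstate dominated by a harmonic label
#'
#' @param oracle from \code{\link{variationalOracle}}.
#' @param state a \code{VibState}.
#' @return energy in cm-1 relative to the variational ground state.
#' @export
oracleEnergy <- function(oracle, state) {
  oracle$values[oracleLevelIndex(oracle, state)]
}

#' Oracle transition moment from the ground state
#'
#' The property operator is expanded to the same Taylor order as in the
#' perturbative machinery and evaluated between numerical eigenvectors.
#'
#' @param oracle from \code{\link{variationalOracle}}.
#' @param state target \code{VibState} (harmonic label of the eigenstate).
#' @param surface a \code{PropertySurface}.
#' @return numeric vector, one entry per component.
#' @export
oracleMoment <- function(oracle, state, surface) {
  lvl <- oracleLevelIndex(oracle, state)
  v0 <- oracle$vectors[, 1]
  vf <- oracle$vectors[, lvl]
  nc <- surface@nComponents
  n <- ncol(oracle$basis)
  out <- numeric(nc)
  for (c_ in seq_len(nc)) {
    pt <- propertyTerms(surface, c_)
    terms <- c(pt$t0, pt$t1, pt$t2)
    ## P matrix column by column on the basis
    acc <- 0
    for (col in seq_len(nrow(oracle$basis))) {
      if (abs(vf[col]) < 1e-12) next
      wf <- applyTerms(oracle$basis[col, ], terms)
      hit <- match(names(wf), oracle$keys)
      ok <- !is.na(hit)
      acc <- acc + sum(v0[hit[ok]] * unname(wf[ok])) * vf[col]
    }
    out[c_] <- acc
  }
  out
}
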