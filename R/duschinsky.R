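## Consistency gate for hybrid schemes that combine harmonic data from one
## electronic-structure level with anharmonic data from another: the
## lower-level normal coordinates are expressed on the basis of the
## higher-level ones, Q^L = J Q^H + K. A near-permutation J with a
## negligible K certifies that the two mode sets describe the same
## vibrations.

## Eckart/Kabsch alignment of geomB onto geomA with atomic masses
eckartRotation <- function(geomA, geomB, masses) {
  wA <- colSums(geomA * masses) / sum(masses)
  wB <- colSums(geomB * masses) / sum(masses)
  A <- sweep(geomA, 2, wA)
  B <- sweep(geomB, 2, wB)
  C <- t(B * masses) %*% A
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, comA = wA, comB = wB)
}

#' Duschinsky transformation between two sets of normal modes
#'
#' Computes the rotation matrix J and shift vector K relating the normal
#' coordinates of a lower electronic-structure level to those of a higher
#' (reference) one, after internal Eckart alignment of the two geometries.
#' K is reported but never used for pass/fail (any non-rigid geometry
#' change contaminates it); a warning is emitted when its norm exceeds
#' \code{kWarn}.
#'
#' @param Lhigh,Llow mass-weighted normal-mode matrices (3*nAtoms x nModes,
#'   orthonormal columns), higher and lower level.
#' @param geomHigh,geomLow equilibrium geometries (nAtoms x 3, Angstrom),
#'   same atom ordering. Optional when the frames already coincide.
#' @param masses atomic masses (amu); default unit masses.
#' @param kWarn warning threshold on ||K||.
#' @return a \code{DuschinskyResult}.
#' @export
duschinsky <- function(Lhigh, Llow, geomHigh = NULL, geomLow = NULL,
                       masses = NULL, kWarn = 1e-3) {
  if (nrow(Lhigh) != nrow(Llow))
    stop("atom-count mismatch between the two mode sets")
  nAt <- nrow(Lhigh) / 3L
  if (is.null(masses)) masses <- rep(1, nAt)
  if (length(masses) != nAt) stop("masses must have one entry per atom")
  K <- rep(0, ncol(Lhigh))
  if (!is.null(geomHigh) && !is.null(geomLow)) {
    al <- eckartRotation(geomHigh, geomLow, masses)
    geomLowR <- sweep(geomLow, 2, al$comB) %*% t(al$R)
    geomHighC <- sweep(geomHigh, 2, al$comA)
    ## rotate the lower-level modes atom-block-wise
    Llow <- do.call(rbind, lapply(seq_len(nAt), function(a) {
      rows <- (3 * a - 2):(3 * a)
      al$R %*% Llow[rows, , drop = FALSE]
    }))
    disp <- sqrt(rep(masses, each = 3L)) *
      as.numeric(t(geomLowR - geomHighC))
    K <- as.numeric(t(Lhigh) %*% disp)
  }
  J <- t(Lhigh) %*% Llow
  res <- new("DuschinskyResult", J = J, K = K,
             rowMax = apply(J^2, 1, max), colMax = apply(J^2, 2, max))
  if (sqrt(sum(K^2)) > kWarn)
    warning(sprintf("Duschinsky shift |K| = %.3g exceeds %.3g",
                    sqrt(sum(K^2)), kWarn))
  res
}

#' Mode-correspondence gate on a Duschinsky matrix
#'
#' Passes iff every row and every column of J has exactly one squared
#' element above the threshold; on pass the induced mode mapping is
#' returned, on failure the offending modes are listed.
#'
#' @param result a \code{DuschinskyResult}.
#' @param threshold squared-element threshold (default 0.9).
#' @return list(pass =, mapping = integer vector high -> low on pass,
#'   offending = integer mode indices on failure).
#' @export
checkCorrespondence <- function(result, threshold = 0.9) {
  J2 <- result@J^2
  rowsOK <- rowSums(J2 > threshold) == 1L
  colsOK <- colSums(J2 > threshold) == 1L
  if (all(rowsOK) && all(colsOK)) {
    list(pass = TRUE, mapping = apply(J2, 1, which.max),
         offending = integer(0))
  } else {
    list(pass = FALSE, mapping = NULL,
         offending = sort(unique(c(which(!rowsOK), which(!colsOK)))))
  }
}
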