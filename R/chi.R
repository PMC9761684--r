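## The VPT2 anharmonicity matrix. Working formulas (cm-1, dimensionless
## normal coordinates; k = cubic, K = semidiagonal quartic constants):
##
##   chi_ii = K_iiii/16
##          - (1/16) sum_k k_iik^2 [ 2/w_k - (1/2)/(2w_i - w_k)
##                                          + (1/2)/(2w_i + w_k) ]
##   chi_ij = K_iijj/4 - (1/4) sum_k k_iik k_jjk / w_k
##          - (1/8) sum_k k_ijk^2 [ 1/(w_i+w_j+w_k) + 1/(w_i+w_k-w_j)
##                                 + 1/(w_j+w_k-w_i) - 1/(w_i+w_j-w_k) ]
##          + (w_i^2 + w_j^2)/(w_i w_j) * sum_axis B_eq (zeta_ij)^2
##
## The partial-fraction form exposes each Fermi-resonance denominator as a
## separate term, which is the granularity at which DVPT2 removes them:
## the triad (a; b, c) with w_a ~ w_b + w_c owns every occurrence of the
## denominator +-(w_b + w_c - w_a) across the chi elements.

fermiTriadKey <- function(a, b, c) {
  bc <- sort(c(b, c))
  paste(a, bc[1], bc[2], sep = ".")
}

#' Compute the anharmonic chi matrix and zero-point correction
#'
#' @param harm a \code{HarmonicModel}.
#' @param field an \code{AnharmonicField} (semidiagonal quartic required).
#' @param resdb a \code{ResonanceDB} (required for DVPT2; terms whose
#'   denominator corresponds to an accepted Fermi resonance are omitted and
#'   logged in \code{removedTerms}).
#' @param mode "VPT2" (plain; an exactly zero denominator is an error),
#'   "DVPT2" (resonant terms removed), or "HDCPT2" (near-singular
#'   denominators replaced by a smooth degeneracy-corrected form so every
#'   chi element is finite for any input).
#' @return a \code{ChiMatrix}.
#' @export
computeChi <- function(harm, field, resdb = NULL,
                       mode = c("VPT2", "DVPT2", "HDCPT2")) {
  mode <- match.arg(mode)
  omega <- harm@omega
  n <- length(omega)
  if (mode == "DVPT2" && is.null(resdb))
    stop("DVPT2 requires a ResonanceDB")
  removedSet <- character(0)
  if (!is.null(resdb) && nrow(resdb@table)) {
    tb <- resdb@table
    fr <- tb[tb$kind %in% c("FERMI_I", "FERMI_II"), , drop = FALSE]
    if (nrow(fr))
      removedSet <- unique(mapply(fermiTriadKey, fr$i, fr$j, fr$k))
  }
  removed <- list()
  logRemoval <- function(what, a, b, c) {
    removed[[length(removed) + 1L]] <<-
      data.frame(element = what, triad = fermiTriadKey(a, b, c))
  }
  ## resonant reciprocal: DVPT2 removes accepted triads; HDCPT2 regularizes;
  ## VPT2 errors on an exact zero.
  resRecip <- function(D, W, a, b, c, what) {
    if (mode == "DVPT2" && fermiTriadKey(a, b, c) %in% removedSet) {
      logRemoval(what, a, b, c)
      return(0)
    }
    if (mode == "HDCPT2") return(hdcptTerm(D, W) / (W * W))
    if (D == 0)
      stop(sprintf("exact degeneracy in VPT2 denominator for triad (%d;%d,%d)",
                   a, b, c), call. = FALSE)
    1 / D
  }
  needQuartic <- function(...) {
    idx <- c(...)
    if (!field@hasFullQuartic && !isSemidiagonal(idx))
      stop("missing quartic constant (", paste(idx, collapse = ","), ")")
    quarticConstant(field, ..., missingAsZero = TRUE)
  }
  chi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    acc <- needQuartic(i, i, i, i) / 16
    for (k in seq_len(n)) {
      kiik <- cubicConstant(field, i, i, k)
      if (kiik == 0) next
      W <- abs(kiik) / 4 # type-I 2x2 coupling <2_i|H|1_k>
      rr <- if (k == i) 1 / omega[i] else
        resRecip(2 * omega[i] - omega[k], W, k, i, i, sprintf("chi[%d,%d]", i, i))
      acc <- acc - (kiik^2 / 16) *
        (2 / omega[k] + 0.5 / (2 * omega[i] + omega[k]) - 0.5 * rr)
    }
    chi[i, i] <- acc
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        acc <- needQuartic(i, i, j, j) / 4
        for (k in seq_len(n)) {
          kiik <- cubicConstant(field, i, i, k)
          kjjk <- cubicConstant(field, j, j, k)
          if (kiik != 0 && kjjk != 0)
            acc <- acc - kiik * kjjk / (4 * omega[k])
          kijk <- cubicConstant(field, i, j, k)
          if (kijk != 0) {
            W <- abs(kijk) / (2 * sqrt(2))
            what <- sprintf("chi[%d,%d]", i, j)
            d1 <- 1 / (omega[i] + omega[j] + omega[k])
            ## D3-type: resonant when w_j ~ w_i + w_k, triad (j; i, k)
            d3 <- if (j == k) 1 / omega[i] else
              resRecip(omega[i] + omega[k] - omega[j], W, j, i, k, what)
            ## D4-type: resonant when w_i ~ w_j + w_k, triad (i; j, k)
            d4 <- if (i == k) 1 / omega[j] else
              resRecip(omega[j] + omega[k] - omega[i], W, i, j, k, what)
            ## D2-type: resonant when w_k ~ w_i + w_j, triad (k; i, j)
            d2 <- if (k == i) 1 / omega[j] else if (k == j) 1 / omega[i] else
              resRecip(omega[i] + omega[j] - omega[k], W, k, i, j, what)
            acc <- acc - (kijk^2 / 8) * (d1 + d3 + d4 - d2)
          }
        }
        cor <- 0
        for (ax in 1:3)
          cor <- cor + harm@Beq[ax] * harm@zeta[ax, i, j]^2
        acc <- acc + cor * (omega[i]^2 + omega[j]^2) / (omega[i] * omega[j])
        chi[i, j] <- chi[j, i] <- acc
      }
    }
  }
  removedDf <- if (length(removed)) unique(do.call(rbind, removed)) else
    data.frame(element = character(0), triad = character(0))
  new("ChiMatrix", chi = chi, eps0 = zeroPointCorrection(omega, field),
      omega = omega, removedTerms = removedDf, mode = mode)
}

## Anharmonic correction to the zero-point energy (total ZPE =
## sum(omega)/2 + eps0), by direct second-order perturbation theory on the
## ground state. Excludes the Coriolis ZPE piece and the Watson U term.
zeroPointCorrection <- function(omega, field) {
  n <- length(omega)
  e <- 0
  for (i in seq_len(n)) e <- e + quarticConstant(field, i, i, i, i,
                                                 missingAsZero = TRUE) / 32
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      e <- e + quarticConstant(field, i, i, j, j, missingAsZero = TRUE) / 16
  ## |1_k> channel: amplitude sum_i k_iik/(4 sqrt(2))
  for (k in seq_len(n)) {
    A <- sum(vapply(seq_len(n), function(i) cubicConstant(field, i, i, k),
                    numeric(1)))
    e <- e - A^2 / (32 * omega[k])
  }
  ## |3_i> channel
  for (i in seq_len(n))
    e <- e - cubicConstant(field, i, i, i)^2 / (144 * omega[i])
  ## |2_i 1_k> channels (i != k)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    kiik <- cubicConstant(field, i, i, k)
    if (kiik != 0) e <- e - kiik^2 / (16 * (2 * omega[i] + omega[k]))
  }
  ## |1_i 1_j 1_k> channels (i < j < k)
  if (n > 2)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      kijk <- cubicConstant(field, i, j, k)
      if (kijk != 0)
        e <- e - kijk^2 / (8 * (omega[i] + omega[j] + omega[k]))
    }
  e
}

#' Anharmonic state energy relative to the ground state
#'
#' Dunham-type expansion: with quanta v,
#' \deqn{\nu(v) = \sum_i v_i\omega_i + \sum_i \chi_{ii}(v_i^2+v_i) +
#'   \sum_{i<j} \chi_{ij}\,(v_i v_j + (v_i+v_j)/2)}
#' which is the (v+1/2)-product convention with the ground state subtracted.
#'
#' @param chiMat a \code{ChiMatrix}.
#' @param state a \code{VibState}.
#' @return energy in cm-1 relative to the ground state.
#' @export
stateEnergy <- function(chiMat, state) {
  v <- denseQuanta(state, length(chiMat@omega))
  omega <- chiMat@omega
  chi <- chiMat@chi
  e <- sum(v * omega) + sum(diag(chi) * (v^2 + v))
  n <- length(omega)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      e <- e + chi[i, j] * (v[i] * v[j] + (v[i] + v[j]) / 2)
  e
}
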