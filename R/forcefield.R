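## Canonical sparse storage of cubic/quartic force constants.
## Values are stored once per sorted index tuple; retrieval of any index
## order returns the canonical value (full permutational symmetry).

ffKey <- function(idx) paste(sort(as.integer(idx)), collapse = ".")

keyIdx <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1]])

#' Is a quartic index pattern semidiagonal?
#'
#' Semidiagonal patterns have at most three distinct indices with at least
#' one repeated (iiii, iijj, iiij, iijk); they are the patterns available
#' from two-step numerical differentiation of analytic Hessians.
#'
#' @param idx integer vector of four mode indices (any order).
#' @return logical.
#' @export
isSemidiagonal <- function(idx) {
  stopifnot(length(idx) == 4L)
  length(unique(idx)) <= 3L
}

#' Construct an AnharmonicField
#'
#' @param nModes number of modes.
#' @param cubic data.frame with columns i, j, k, value (indices in any
#'   order), or NULL for none.
#' @param quartic data.frame with columns i, j, k, l, value, or NULL.
#' @param hasFullQuartic allow off-semidiagonal quartic entries.
#' @return an \code{AnharmonicField}.
#' @export
anharmonicField <- function(nModes, cubic = NULL, quartic = NULL,
                            hasFullQuartic = FALSE) {
  nModes <- as.integer(nModes)
  cub <- numeric(0)
  if (!is.null(cubic) && nrow(cubic)) {
    keys <- apply(cubic[, c("i", "j", "k"), drop = FALSE], 1L, ffKey)
    cub <- tapply(cubic$value, keys, function(v) {
      if (max(v) - min(v) > 1e-9)
        stop("conflicting values for cubic constant ", names(v)[1])
      v[1]
    })
    cub <- stats::setNames(as.numeric(cub), names(cub))
  }
  qua <- numeric(0)
  if (!is.null(quartic) && nrow(quartic)) {
    keys <- apply(quartic[, c("i", "j", "k", "l"), drop = FALSE], 1L, ffKey)
    qua <- tapply(quartic$value, keys, function(v) v[1])
    qua <- stats::setNames(as.numeric(qua), names(qua))
  }
  new("AnharmonicField", nModes = nModes, cubic = cub, quartic = qua,
      hasFullQuartic = isTRUE(hasFullQuartic))
}

#' Retrieve a cubic force constant
#'
#' Permutation-invariant lookup; absent entries are 0 (a cubic field is
#' always complete in the sense that unmeasured constants are zero).
#'
#' @param field an \code{AnharmonicField}.
#' @param i,j,k mode indices in any order.
#' @return the constant in cm-1.
#' @export
cubicConstant <- function(field, i, j, k) {
  v <- field@cubic[ffKey(c(i, j, k))]
  if (is.na(v)) 0 else unname(v)
}

#' Retrieve a semidiagonal quartic force constant
#'
#' Permutation-invariant lookup. Off-semidiagonal patterns are unavailable
#' unless the field carries a full quartic set: by default they signal an
#' error instead of silently returning zero, unless \code{missingAsZero}.
#'
#' @param field an \code{AnharmonicField}.
#' @param i,j,k,l mode indices in any order.
#' @param missingAsZero explicitly treat unavailable patterns as 0.
#' @return the constant in cm-1.
#' @export
quarticConstant <- function(field, i, j, k, l, missingAsZero = FALSE) {
  idx <- c(i, j, k, l)
  if (!field@hasFullQuartic && !isSemidiagonal(idx)) {
    if (missingAsZero) return(0)
    stop(sprintf("quartic constant (%s) is off-semidiagonal and unavailable",
                 paste(idx, collapse = ",")), call. = FALSE)
  }
  v <- field@quartic[ffKey(idx)]
  if (is.na(v)) 0 else unname(v)
}

#' Check redundantly computed force constants for consistency
#'
#' Independent numerical estimates of the same constant (obtained from
#' displacements along different modes) must agree; fluctuations beyond the
#' tolerance flag a failure to reach the true minimum or instabilities in
#' the underlying electronic-structure data.
#'
#' @param estimates named list: key = index tuple string ("i.j.k"), value =
#'   numeric vector of independent estimates.
#' @param tol acceptance tolerance in cm-1 (default 1).
#' @return list with \code{pass}, a per-constant \code{report} data.frame
#'   (max deviation, canonical mean value) and \code{canonical} values.
#' @export
validateForceField <- function(estimates, tol = 1.0) {
  if (tol <= 0) stop("tol must be positive")
  if (!length(estimates)) stop("no estimate groups supplied")
  rows <- lapply(names(estimates), function(key) {
    v <- estimates[[key]]
    if (!length(v)) stop("empty estimate group for ", key)
    data.frame(indices = key, n = length(v),
               deviation = max(v) - min(v),
               canonical = mean(v), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(pass = all(report$deviation < tol), report = report,
       canonical = stats::setNames(report$canonical, report$indices))
}

#' Restrict the anharmonic treatment to a set of active modes
#'
#' Zeroes every cubic, quartic and property-derivative entry carrying a mode
#' index outside \code{active} (reduced-dimensionality masking, e.g. to
#' exclude hindered-rotor modes whose torsional motion is poorly described
#' by a quartic force field). Harmonic data are untouched; masking is
#' idempotent.
#'
#' @param bundle a \code{VibData}.
#' @param active integer vector of active mode indices.
#' @return the masked \code{VibData}.
#' @export
maskActiveModes <- function(bundle, active) {
  n <- length(bundle@harmonic@omega)
  active <- as.integer(active)
  if (!length(active)) stop("active mode set must not be empty")
  if (any(active < 1L | active > n)) stop("active mode indices out of range")
  keep <- function(keys) {
    vapply(keys, function(k) all(keyIdx(k) %in% active), logical(1))
  }
  f <- bundle@field
  f@cubic <- f@cubic[keep(names(f@cubic))]
  f@quartic <- f@quartic[keep(names(f@quartic))]
  props <- lapply(bundle@properties, function(p) {
    inact <- setdiff(seq_len(n), active)
    if (length(inact)) {
      p@P1[inact, ] <- 0
      p@P2[inact, , ] <- 0
      p@P2[, inact, ] <- 0
      if (length(p@P3))
        p@P3 <- p@P3[vapply(names(p@P3),
                            function(k) all(keyIdx(k) %in% active), logical(1))]
    }
    p
  })
  new("VibData", harmonic = bundle@harmonic, field = f, properties = props)
}
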