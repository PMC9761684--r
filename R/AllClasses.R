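#' @import methods
NULL

## Central S4 containers for anharmonic vibrational calculations.
## Energies and force constants are exchanged in cm-1 over dimensionless
## normal coordinates; property derivatives are kept in atomic units and
## converted only in the spectra layer.

#' Harmonic description of a molecular system
#'
#' Holds the harmonic wavenumbers, the mass-weighted normal-mode matrix,
#' equilibrium rotational constants and Coriolis couplings. Mode indexing is
#' 1-based, ascending by wavenumber.
#'
#' @slot nAtoms number of atoms.
#' @slot linear whether the molecule is linear (3N-5 modes instead of 3N-6).
#' @slot omega harmonic wavenumbers in cm-1, nondecreasing, all positive.
#' @slot L mass-weighted normal-mode matrix, 3*nAtoms x nModes, unit-norm
#'   columns with the largest-magnitude element of each column positive.
#' @slot Beq equilibrium rotational constants (3-vector, cm-1).
#' @slot zeta Coriolis coupling tensor, 3 x nModes x nModes, antisymmetric in
#'   the mode indices for each axis.
#' @slot geometry optional Cartesian coordinates (nAtoms x 3, Angstrom).
#' @exportClass HarmonicModel
setClass("HarmonicModel",
  representation(
    nAtoms = "integer",
    linear = "logical",
    omega = "numeric",
    L = "matrix",
    Beq = "numeric",
    zeta = "array",
    geometry = "matrix"
  )
)

setValidity("HarmonicModel", function(object) {
  msgs <- character()
  n <- length(object@omega)
  expected <- modeCount(object@nAtoms, linear = object@linear)
  if (n > expected)
    msgs <- c(msgs, sprintf("at most %d modes possible for %d atoms, got %d",
                            expected, object@nAtoms, n))
  if (any(object@omega <= 0))
    msgs <- c(msgs, sprintf("nonpositive harmonic wavenumbers at modes: %s",
                            paste(which(object@omega <= 0), collapse = ", ")))
  if (is.unsorted(object@omega))
    msgs <- c(msgs, "omega must be nondecreasing")
  if (!all(dim(object@L) == c(3L * object@nAtoms, n)))
    msgs <- c(msgs, "L must be 3*nAtoms x nModes")
  nrm <- sqrt(colSums(object@L^2))
  if (length(nrm) && any(abs(nrm - 1) > 1e-6))
    msgs <- c(msgs, "columns of L must have unit Euclidean norm")
  if (length(object@Beq) != 3L)
    msgs <- c(msgs, "Beq must have length 3")
  if (!all(dim(object@zeta) == c(3L, n, n))) {
    msgs <- c(msgs, "zeta must be 3 x nModes x nModes")
  } else {
    for (ax in 1:3) {
      s <- object@zeta[ax, , ] + t(object@zeta[ax, , ])
      if (length(s) && max(abs(s)) >= 1e-8) {
        msgs <- c(msgs, sprintf("zeta[%d,,] is not antisymmetric", ax))
        break
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Number of vibrational normal modes
#'
#' @param nAtoms number of atoms.
#' @param linear logical; TRUE for a linear molecule.
#' @return 3*nAtoms - 6 (nonlinear) or 3*nAtoms - 5 (linear).
#' @examples
#' modeCount(10) # 24
#' modeCount(42) # 120
#' @export
modeCount <- function(nAtoms, linear = FALSE) {
  nAtoms <- as.integer(nAtoms)
  stopifnot(nAtoms >= 2L)
  3L * nAtoms - if (linear) 5L else 6L
}

#' Cubic and semidiagonal quartic force constants
#'
#' Sparse canonical storage (one value per sorted index tuple, cm-1).
#' Quartic entries are restricted to semidiagonal patterns (at least one
#' repeated index, at most three distinct indices) unless
#' \code{hasFullQuartic} is set. Querying an off-semidiagonal quartic with
#' \code{hasFullQuartic = FALSE} signals an "unavailable" condition rather
#' than silently returning zero.
#'
#' @slot nModes number of modes the field refers to.
#' @slot cubic named numeric; names are sorted triples "i.j.k".
#' @slot quartic named numeric; names are sorted quadruples "i.j.k.l".
#' @slot hasFullQuartic logical availability flag for off-semidiagonal terms.
#' @exportClass AnharmonicField
setClass("AnharmonicField",
  representation(
    nModes = "integer",
    cubic = "numeric",
    quartic = "numeric",
    hasFullQuartic = "logical"
  )
)

setValidity("AnharmonicField", function(object) {
  msgs <- character()
  chk <- function(keys, k, label) {
    out <- character()
    for (key in keys) {
      idx <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
      if (length(idx) != k || is.unsorted(idx) ||
          any(idx < 1L) || any(idx > object@nModes))
        out <- c(out, sprintf("malformed %s key '%s'", label, key))
    }
    out
  }
  msgs <- c(msgs, chk(names(object@cubic), 3L, "cubic"))
  msgs <- c(msgs, chk(names(object@quartic), 4L, "quartic"))
  if (!object@hasFullQuartic) {
    for (key in names(object@quartic)) {
      idx <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
      if (!isSemidiagonal(idx))
        msgs <- c(msgs, sprintf("off-semidiagonal quartic '%s' stored without hasFullQuartic", key))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Taylor data for a molecular property surface
#'
#' Implements the generic ladder-operator property expansion: \code{S = +1}
#' for properties that are functions of the normal coordinates (electric
#' dipole), \code{S = -1} for properties linear in the conjugate momenta
#' (magnetic dipole / atomic axial tensor for VCD). For \code{S = -1} the
#' derivative indices do not fully permute: \code{P2[i, j, ]} is the mixed
#' derivative with respect to coordinate i and momentum j, and third
#' derivatives carry the momentum index last.
#'
#' @slot name property label, e.g. "electric_dipole".
#' @slot nComponents number of Cartesian components (3 for vectors).
#' @slot S +1 (coordinate-type) or -1 (momentum-type).
#' @slot s0,s1,s2,s3 constant prefactors of the expansion (default 1).
#' @slot P0 equilibrium value per component.
#' @slot P1 first derivatives, nModes x nComponents.
#' @slot P2 second derivatives, nModes x nModes x nComponents.
#' @slot P3 sparse third derivatives; named list, keys "i.j.k" (semidiagonal
#'   patterns only), values numeric vectors of length nComponents.
#' @slot units unit string (atomic units internally).
#' @exportClass PropertySurface
setClass("PropertySurface",
  representation(
    name = "character",
    nComponents = "integer",
    S = "numeric",
    s0 = "numeric", s1 = "numeric", s2 = "numeric", s3 = "numeric",
    P0 = "numeric",
    P1 = "matrix",
    P2 = "array",
    P3 = "list",
    units = "character"
  ),
  prototype(S = 1, s0 = 1, s1 = 1, s2 = 1, s3 = 1, units = "au")
)

setValidity("PropertySurface", function(object) {
  msgs <- character()
  nc <- object@nComponents
  if (!object@S %in% c(1, -1)) msgs <- c(msgs, "S must be +1 or -1")
  if (length(object@P0) != nc) msgs <- c(msgs, "P0 length != nComponents")
  if (ncol(object@P1) != nc) msgs <- c(msgs, "P1 must be nModes x nComponents")
  n <- nrow(object@P1)
  if (!all(dim(object@P2) == c(n, n, nc)))
    msgs <- c(msgs, "P2 must be nModes x nModes x nComponents")
  if (object@S == 1) {
    for (c_ in seq_len(nc)) {
      m <- object@P2[, , c_]
      if (length(m) && max(abs(m - t(m))) > 1e-10) {
        msgs <- c(msgs, "P2 must be index-symmetric for S = +1")
        break
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' A vibrational state in the harmonic basis
#'
#' Sparse vector of quanta: a named integer vector mapping mode index to a
#' positive quantum count. The ground state is the empty map.
#'
#' @slot quanta named integer vector (names = mode indices, values > 0).
#' @exportClass VibState
setClass("VibState", representation(quanta = "integer"))

setValidity("VibState", function(object) {
  q <- object@quanta
  if (length(q) == 0L) return(TRUE)
  if (is.null(names(q))) return("quanta must be named by mode index")
  if (any(q <= 0L)) return("quantum counts must be positive")
  modes <- as.integer(names(q))
  if (any(is.na(modes)) || any(modes < 1L)) return("invalid mode indices")
  if (is.unsorted(modes, strictly = TRUE)) return("modes must be strictly increasing")
  TRUE
})

#' Construct a VibState
#'
#' @param modes integer vector of mode indices.
#' @param quanta integer vector of quantum counts (same length), default 1.
#' @return a \code{VibState}.
#' @examples
#' vibState(3)          # fundamental of mode 3
#' vibState(2, 2)       # first overtone of mode 2
#' vibState(c(1, 4))    # 1+1 combination
#' vibState(integer(0)) # ground state
#' @export
vibState <- function(modes = integer(0), quanta = rep(1L, length(modes))) {
  modes <- as.integer(modes); quanta <- as.integer(quanta)
  stopifnot(length(modes) == length(quanta))
  o <- order(modes)
  q <- quanta[o]
  names(q) <- modes[o]
  new("VibState", quanta = q)
}

#' Complete input bundle for an anharmonic calculation
#'
#' @slot harmonic a \code{HarmonicModel}.
#' @slot field an \code{AnharmonicField}.
#' @slot properties list of \code{PropertySurface} objects.
#' @exportClass VibData
setClass("VibData",
  representation(
    harmonic = "HarmonicModel",
    field = "AnharmonicField",
    properties = "list"
  )
)

setValidity("VibData", function(object) {
  if (object@field@nModes != length(object@harmonic@omega))
    return("field nModes inconsistent with harmonic model")
  for (p in object@properties) {
    if (!is(p, "PropertySurface")) return("properties must be PropertySurface objects")
    if (nrow(p@P1) != length(object@harmonic@omega))
      return(sprintf("property '%s' has wrong number of modes", p@name))
  }
  TRUE
})

#' Anharmonicity-constant matrix and zero-point correction
#'
#' @slot chi symmetric nModes x nModes matrix, cm-1.
#' @slot eps0 anharmonic zero-point correction (total ZPE = sum(omega)/2 + eps0), cm-1.
#' @slot omega harmonic wavenumbers used, cm-1.
#' @slot removedTerms data.frame ledger of resonant terms excluded (DVPT2).
#' @slot mode one of "VPT2", "DVPT2", "HDCPT2".
#' @exportClass ChiMatrix
setClass("ChiMatrix",
  representation(
    chi = "matrix",
    eps0 = "numeric",
    omega = "numeric",
    removedTerms = "data.frame",
    mode = "character"
  )
)

setValidity("ChiMatrix", function(object) {
  m <- object@chi
  if (nrow(m) != ncol(m)) return("chi must be square")
  if (length(m) && max(abs(m - t(m))) > 1e-9) return("chi must be symmetric")
  if (object@mode == "HDCPT2" && any(!is.finite(m)))
    return("chi must be finite under HDCPT2 regularization")
  TRUE
})

#' Accepted resonances, indexed by type and mode
#'
#' The \code{table} records one row per accepted candidate: the resonance
#' kind (FERMI_I, FERMI_II, DD11, DD22, DD211), the mode tuple, the harmonic
#' energy gap, the coupling (cm-1), the per-scheme index values and which
#' scheme(s) triggered acceptance. \code{coefCache} stores the perturbative
#' wave-function coefficients computed during the analysis for reuse by the
#' pseudoeigenvector and transition-moment machinery.
#'
#' @slot table data.frame of accepted resonances.
#' @slot candidates data.frame of all tested candidates (diagnostics).
#' @slot config the threshold configuration used.
#' @slot coefCache environment cache of perturbative coefficients.
#' @exportClass ResonanceDB
setClass("ResonanceDB",
  representation(
    table = "data.frame",
    candidates = "data.frame",
    config = "list",
    coefCache = "environment"
  )
)

#' Connected clusters of resonant states
#'
#' @slot polyads list; each element has \code{states} (character keys),
#'   \code{couplings} (symmetric matrix, cm-1).
#' @slot stateSpace character vector of all state keys considered.
#' @exportClass PolyadDB
setClass("PolyadDB",
  representation(polyads = "list", stateSpace = "character")
)

#' Result of the per-polyad variational step
#'
#' @slot blocks list; per polyad: states, matrix, values (ascending GVPT2
#'   energies), vectors (orthonormal eigenvectors, phase-fixed), assignment.
#' @slot energies named numeric: GVPT2 energy per state key (singletons pass
#'   through unchanged).
#' @slot dvpt2 named numeric: the input DVPT2 energies.
#' @exportClass GVPT2Result
setClass("GVPT2Result",
  representation(blocks = "list", energies = "numeric", dvpt2 = "numeric")
)

#' A broadened band shape on a wavenumber grid
#'
#' @slot grid strictly increasing wavenumber grid (cm-1).
#' @slot values curve values on the grid.
#' @slot sticks the (position, strength) sticks that were convolved.
#' @slot kind spectrum kind ("IR", "VCD", "generic").
#' @slot shape broadening kernel ("lorentzian" or "gaussian").
#' @slot hwhm half-width at half-maximum, cm-1.
#' @slot shift rigid shift applied to stick positions, cm-1.
#' @exportClass BandShape
setClass("BandShape",
  representation(
    grid = "numeric", values = "numeric", sticks = "data.frame",
    kind = "character", shape = "character", hwhm = "numeric",
    shift = "numeric"
  )
)

setValidity("BandShape", function(object) {
  if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
  if (any(!is.finite(object@values))) return("curve values must be finite")
  TRUE
})

#' Duschinsky consistency-check result
#'
#' @slot J Duschinsky rotation matrix (nModes x nModes).
#' @slot K shift vector in dimensionless normal coordinates of the reference.
#' @slot rowMax,colMax maximum squared element per row / column.
#' @exportClass DuschinskyResult
setClass("DuschinskyResult",
  representation(J = "matrix", K = "numeric", rowMax = "numeric",
                 colMax = "numeric")
)
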