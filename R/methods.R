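#' @include AllClasses.R
NULL

#' Number of modes of an object
#' @param x a \code{HarmonicModel}, \code{AnharmonicField}, \code{VibData}
#'   or \code{ChiMatrix}.
#' @return integer.
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' @rdname nModes
#' @export
setMethod("nModes", "HarmonicModel", function(x) length(x@omega))

#' @rdname nModes
#' @export
setMethod("nModes", "AnharmonicField", function(x) x@nModes)

#' @rdname nModes
#' @export
setMethod("nModes", "VibData", function(x) length(x@harmonic@omega))

#' @rdname nModes
#' @export
setMethod("nModes", "ChiMatrix", function(x) nrow(x@chi))

#' Harmonic wavenumbers (cm-1)
#' @param x a \code{HarmonicModel} or \code{VibData}.
#' @return numeric vector.
#' @export
setGeneric("harmonicWavenumbers",
           function(x) standardGeneric("harmonicWavenumbers"))

#' @rdname harmonicWavenumbers
#' @export
setMethod("harmonicWavenumbers", "HarmonicModel", function(x) x@omega)

#' @rdname harmonicWavenumbers
#' @export
setMethod("harmonicWavenumbers", "VibData", function(x) x@harmonic@omega)

#' Chi matrix values
#' @param x a \code{ChiMatrix}.
#' @return symmetric numeric matrix (cm-1).
#' @export
chiValues <- function(x) x@chi

#' Accepted-resonance table
#' @param x a \code{ResonanceDB}.
#' @return data.frame.
#' @export
resonanceTable <- function(x) x@table

#' Polyad list
#' @param x a \code{PolyadDB}.
#' @return list of polyads (states + coupling matrix).
#' @export
polyadList <- function(x) x@polyads

#' GVPT2 energies per state label
#' @param x a \code{GVPT2Result}.
#' @return named numeric (cm-1).
#' @export
gvpt2Energies <- function(x) x@energies

setMethod("show", "HarmonicModel", function(object) {
  cat(sprintf("HarmonicModel: %d atoms, %d modes, %.1f-%.1f cm-1%s\n",
              object@nAtoms, length(object@omega), min(object@omega),
              max(object@omega),
              if (max(abs(object@zeta)) > 0) ", Coriolis" else ""))
})

setMethod("show", "AnharmonicField", function(object) {
  cat(sprintf("AnharmonicField: %d modes, %d cubic, %d quartic%s\n",
              object@nModes, length(object@cubic), length(object@quartic),
              if (object@hasFullQuartic) " (full)" else " (semidiagonal)"))
})

setMethod("show", "PropertySurface", function(object) {
  cat(sprintf("PropertySurface '%s': %d components, S = %+d, units %s\n",
              object@name, object@nComponents, object@S, object@units))
})

setMethod("show", "VibState", function(object) {
  cat("VibState:", stateLabel(object), "\n")
})

setMethod("show", "VibData", function(object) {
  show(object@harmonic)
  show(object@field)
  for (p in object@properties) show(p)
})

setMethod("show", "ChiMatrix", function(object) {
  cat(sprintf("ChiMatrix (%s): %d modes, eps0 = %.3f cm-1, %d removed terms\n",
              object@mode, nrow(object@chi), object@eps0,
              nrow(object@removedTerms)))
})

setMethod("show", "ResonanceDB", function(object) {
  tb <- object@table
  cat(sprintf("ResonanceDB: %d accepted (%s) of %d candidates\n",
              nrow(tb),
              if (nrow(tb)) paste(names(table(tb$kind)),
                                  table(tb$kind), sep = ":", collapse = ", ")
              else "none",
              nrow(object@candidates)))
})

setMethod("show", "PolyadDB", function(object) {
  sizes <- vapply(object@polyads, function(p) length(p$states), integer(1))
  cat(sprintf("PolyadDB: %d polyads (sizes %s) over %d states\n",
              length(sizes),
              if (length(sizes)) paste(sort(sizes, decreasing = TRUE),
                                       collapse = ",") else "-",
              length(object@stateSpace)))
})

setMethod("show", "GVPT2Result", function(object) {
  cat(sprintf("GVPT2Result: %d coupled blocks, %d states\n",
              length(object@blocks), length(object@energies)))
})

setMethod("show", "BandShape", function(object) {
  cat(sprintf("BandShape (%s, %s, hwhm %.1f): %d points on [%.1f, %.1f] cm-1\n",
              object@kind, object@shape, object@hwhm, length(object@grid),
              min(object@grid), max(object@grid)))
})

setMethod("show", "DuschinskyResult", function(object) {
  cat(sprintf("DuschinskyResult: %d modes, min row max-sq %.3f, |K| = %.3g\n",
              nrow(object@J), min(object@rowMax), sqrt(sum(object@K^2))))
})
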