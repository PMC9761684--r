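## Stick spectra -> broadened band shapes. Unit conversions are pinned here
## and nowhere else; property moments arrive in atomic units.

#' Physical conversion constants used by the spectra layer
#'
#' \itemize{
#' \item \code{dipoleStrength}: (e a0)^2 in 10^-40 esu^2 cm^2 per atomic
#'   unit of squared electric transition dipole.
#' \item \code{rotatoryStrength}: e a0 * (e hbar / m_e) in 10^-44 esu^2 cm^2
#'   per atomic unit of electric x magnetic transition-moment product.
#' \item \code{epsilon}: 8 pi^3 N_A / (3000 h c ln 10) in the units that
#'   turn nu * D[esu^2 cm^2] * lineshape[cm] into a molar absorptivity
#'   (L mol^-1 cm^-1); the classic inverse relation is
#'   D = 91.86e-40 * integral(eps/nu dnu).
#' }
#' @return named list of constants.
#' @export
spectroConstants <- function() {
  ea0 <- 2.5417464519e-18      # esu cm per atomic unit of electric dipole
  ehbarme <- 1.85480201e-20    # erg/G per atomic unit of magnetic dipole
  list(
    dipoleStrength = ea0^2 * 1e40,        # 6.46047e4
    rotatoryStrength = ea0 * ehbarme * 1e44, # 4.71444e6
    epsilon = 1.08862e-2,     # 1.08862e38 * 1e-40, for D in 1e-40 esu^2 cm^2
    deltaEpsilon = 4.35448e-6 # 4 * 1.08862e38 * 1e-44, for R in 1e-44 esu^2 cm^2
  )
}

#' Convolve a stick spectrum with a broadening kernel
#'
#' Sum over sticks of unit-area Lorentzian or Gaussian kernels scaled by
#' the stick strengths, with positions offset by a rigid shift. Linear in
#' the strengths; by shift equivariance, applying the shift before or after
#' convolution is equivalent on matched grids.
#'
#' @param sticks data.frame with columns \code{position} (cm-1) and
#'   \code{strength} (signed).
#' @param shape "lorentzian" or "gaussian".
#' @param hwhm half-width at half-maximum, cm-1 (> 0).
#' @param grid wavenumber grid; default covers sticks +- 10 hwhm at
#'   0.2 cm-1 spacing.
#' @param shift rigid shift applied to the stick positions, cm-1.
#' @param kind metadata label ("IR", "VCD", "generic").
#' @return a \code{BandShape}.
#' @export
convolveSticks <- function(sticks, shape = c("lorentzian", "gaussian"),
                           hwhm, grid = NULL, shift = 0, kind = "generic") {
  shape <- match.arg(shape)
  if (hwhm <= 0) stop("hwhm must be positive")
  pos <- sticks$position + shift
  if (is.null(grid)) {
    if (!nrow(sticks)) stop("no sticks and no grid supplied")
    grid <- seq(min(pos) - 10 * hwhm, max(pos) + 10 * hwhm, by = 0.2)
  }
  vals <- numeric(length(grid))
  if (nrow(sticks)) {
    if (shape == "lorentzian") {
      for (r in seq_len(nrow(sticks)))
        vals <- vals + sticks$strength[r] *
          (hwhm / pi) / ((grid - pos[r])^2 + hwhm^2)
    } else {
      sigma <- hwhm / sqrt(2 * log(2))
      for (r in seq_len(nrow(sticks)))
        vals <- vals + sticks$strength[r] *
          exp(-(grid - pos[r])^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    }
  }
  new("BandShape", grid = grid, values = vals, sticks = sticks,
      kind = kind, shape = shape, hwhm = hwhm, shift = shift)
}

#' Molar absorptivity / VCD band shapes from a stick table
#'
#' IR intensity is proportional to the band position times the dipole
#' strength (nu * D); VCD to nu * R, with the textbook prefactors from
#' \code{\link{spectroConstants}} applied here and nowhere else.
#'
#' @param table data.frame with columns \code{energy} (cm-1) and \code{D}
#'   (10^-40 esu^2 cm^2) and/or \code{R} (10^-44 esu^2 cm^2).
#' @param kind "IR" (epsilon) or "VCD" (delta epsilon).
#' @param shape,hwhm,grid,shift passed to \code{\link{convolveSticks}}.
#' @return a \code{BandShape}.
#' @export
bandSpectrum <- function(table, kind = c("IR", "VCD"),
                         shape = c("lorentzian", "gaussian"), hwhm = 2,
                         grid = NULL, shift = 0) {
  kind <- match.arg(kind)
  cst <- spectroConstants()
  if (is.null(if (kind == "IR") table$D else table$R))
    stop("stick table lacks the strength column for a ", kind, " spectrum")
  strength <- if (kind == "IR") cst$epsilon * table$energy * table$D
    else cst$deltaEpsilon * table$energy * table$R
  sticks <- data.frame(position = table$energy, strength = strength)
  convolveSticks(sticks, shape, hwhm, grid, shift, kind = kind)
}

#' Compare two band shapes
#'
#' Curves are resampled onto the overlap of their grids by linear
#' interpolation. Returns the normalized inner product (1 for identical
#' curves, -1 for a curve and its negation; symmetric in its arguments)
#' and the signed-area difference.
#'
#' @param a,b \code{BandShape} objects.
#' @return list(overlap =, areaDifference =).
#' @export
compareCurves <- function(a, b) {
  lo <- max(min(a@grid), min(b@grid))
  hi <- min(max(a@grid), max(b@grid))
  if (lo >= hi) stop("curves have disjoint wavenumber ranges")
  x <- seq(lo, hi, length.out = 2048L)
  ya <- stats::approx(a@grid, a@values, x)$y
  yb <- stats::approx(b@grid, b@values, x)$y
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  na <- sqrt(trapz(ya^2)); nb <- sqrt(trapz(yb^2))
  overlap <- if (na == 0 || nb == 0) 0 else trapz(ya * yb) / (na * nb)
  list(overlap = overlap, areaDifference = trapz(ya - yb))
}

#' Export a band shape or stick table
#'
#' Two-column CSV (grid, value) or JSON including metadata.
#'
#' @param shape a \code{BandShape}.
#' @param path output path; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
writeBandShape <- function(shape, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(kind = shape@kind, shape = shape@shape,
                              hwhm = shape@hwhm, shift = shape@shift,
                              grid = shape@grid, values = shape@values),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(wavenumber = shape@grid,
                                value = shape@values),
                     path, row.names = FALSE)
  }
  invisible(path)
}
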