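## VibData interchange: versioned JSON with blocks HARMONIC, CUBIC, QUARTIC
## and PROPERTY:<name>. Energies are exchanged in cm-1 over dimensionless
## normal coordinates; the normal-mode normalization (unit-norm columns,
## largest-magnitude element positive) is declared in the header so any
## consistent source can be mapped.

VIBDATA_FORMAT <- "vibdata-json"
VIBDATA_VERSION <- 1L

#' Write a VibData bundle to a JSON file
#'
#' @param bundle a \code{VibData}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVibData <- function(bundle, path) {
  h <- bundle@harmonic
  f <- bundle@field
  asRows <- function(x, k) {
    if (!length(x)) return(list())
    lapply(names(x), function(key)
      c(as.list(keyIdx(key)), list(unname(x[[key]]))))
  }
  props <- lapply(bundle@properties, function(p) {
    list(
      name = p@name, n_components = p@nComponents, S = p@S,
      s0 = p@s0, s1 = p@s1, s2 = p@s2, s3 = p@s3,
      units = p@units, P0 = p@P0,
      P1 = p@P1, P2 = p@P2,
      P3 = lapply(names(p@P3), function(key)
        list(idx = keyIdx(key), value = p@P3[[key]]))
    )
  })
  doc <- list(
    format = VIBDATA_FORMAT, version = VIBDATA_VERSION,
    units = list(energy = "cm-1", property = "au"),
    normal_mode_convention = "unit-norm columns, largest element positive",
    harmonic = list(
      n_atoms = h@nAtoms, linear = h@linear, omega = h@omega,
      L = h@L, B_eq = h@Beq, zeta = h@zeta,
      geometry = if (nrow(h@geometry)) h@geometry else NULL
    ),
    cubic = asRows(f@cubic, 3L),
    quartic = asRows(f@quartic, 4L),
    has_full_quartic = f@hasFullQuartic,
    properties = props
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a VibData bundle from a JSON file
#'
#' Validates all invariants on load: positive nondecreasing harmonic
#' wavenumbers, antisymmetric Coriolis couplings, unit-norm normal modes
#' and canonical (permutation-symmetric) force-constant storage. Missing
#' optional blocks (zeta, properties, geometry) yield empty defaults with a
#' warning.
#'
#' @param path input file path.
#' @return a validated \code{VibData}.
#' @export
readVibData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed VibData file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(doc$format, VIBDATA_FORMAT))
    stop("malformed header: expected format '", VIBDATA_FORMAT, "'")
  if (is.null(doc$version) || doc$version > VIBDATA_VERSION)
    stop("unsupported VibData version: ", doc$version)
  if (!identical(doc$units$energy, "cm-1"))
    stop("energies must be declared in cm-1")
  hh <- doc$harmonic
  nAtoms <- as.integer(hh$n_atoms)
  omega <- as.numeric(hh$omega)
  n <- length(omega)
  if (any(omega <= 0))
    stop("validation error: nonpositive wavenumbers at modes ",
         paste(which(omega <= 0), collapse = ", "))
  L <- matrix(as.numeric(unlist(hh$L)), nrow = 3L * nAtoms)
  if (ncol(L) != n)
    stop("shape error: L has ", ncol(L), " columns for ", n, " modes")
  if (is.null(hh$zeta)) {
    warning("no Coriolis block; assuming zeta = 0")
    zeta <- array(0, c(3L, n, n))
  } else {
    zeta <- array(as.numeric(unlist(hh$zeta)), c(3L, n, n))
  }
  geometry <- if (is.null(hh$geometry)) matrix(numeric(0), 0L, 3L) else
    matrix(as.numeric(unlist(hh$geometry)), nrow = nAtoms)
  harm <- new("HarmonicModel", nAtoms = nAtoms,
              linear = isTRUE(hh$linear), omega = omega, L = L,
              Beq = as.numeric(hh$B_eq), zeta = zeta, geometry = geometry)
  rows <- function(block, k) {
    if (is.null(block) || !length(block)) return(NULL)
    m <- if (is.matrix(block)) block
      else if (is.data.frame(block)) as.matrix(block)
      else do.call(rbind, lapply(block, unlist))
    if (ncol(m) != k + 1L)
      stop("malformed force-constant row: expected ", k + 1L, " entries")
    df <- as.data.frame(m)
    names(df) <- c(letters[9:(8 + k)], "value")
    df
  }
  field <- anharmonicField(n, cubic = rows(doc$cubic, 3L),
                           quartic = rows(doc$quartic, 4L),
                           hasFullQuartic = isTRUE(doc$has_full_quartic))
  props <- list()
  if (!is.null(doc$properties) && length(doc$properties)) {
    plist <- doc$properties
    if (is.data.frame(plist)) plist <- split(plist, seq_len(nrow(plist)))
    props <- lapply(plist, function(p) {
      if (is.data.frame(p)) p <- as.list(p[1L, ])
      nc <- as.integer(p$n_components)
      P3 <- list()
      if (!is.null(p$P3) && length(p$P3)) {
        entries <- p$P3
        if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
        for (e in entries) {
          idx <- as.integer(unlist(e$idx))
          P3[[paste(idx, collapse = ".")]] <- as.numeric(unlist(e$value))
        }
      }
      new("PropertySurface", name = as.character(p$name), nComponents = nc,
          S = as.numeric(p$S), s0 = as.numeric(p$s0), s1 = as.numeric(p$s1),
          s2 = as.numeric(p$s2), s3 = as.numeric(p$s3),
          P0 = as.numeric(unlist(p$P0)),
          P1 = matrix(as.numeric(unlist(p$P1)), nrow = n),
          P2 = array(as.numeric(unlist(p$P2)), c(n, n, nc)),
          P3 = P3, units = as.character(p$units))
    })
    names(props) <- vapply(props, function(p) p@name, character(1))
  } else {
    warning("no property blocks in bundle")
  }
  out <- new("VibData", harmonic = harm, field = field, properties = props)
  validObject(out@harmonic); validObject(out@field); validObject(out)
  out
}
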