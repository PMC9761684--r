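## End-to-end orchestration: (i) data preparation, (ii) a priori resonance
## analysis, (iii) energy calculation with the variational correction,
## (iv) transition moments and spectra.

#' Energies of the 1- and 2-quanta state space
#'
#' @param chiMat a \code{ChiMatrix}.
#' @return named numeric (state label -> cm-1 relative to ground).
#' @export
stateSpaceEnergies <- function(chiMat) {
  n <- length(chiMat@omega)
  st2 <- twoQuantaStates(n)
  states <- c(lapply(seq_len(n), vibState),
              lapply(seq_len(nrow(st2)), function(r)
                if (st2$a[r] == st2$b[r]) vibState(st2$a[r], 2L) else
                  vibState(c(st2$a[r], st2$b[r]))))
  stats::setNames(vapply(states, function(s) stateEnergy(chiMat, s),
                         numeric(1)),
                  vapply(states, stateLabel, character(1)))
}

#' Full stick table (energies, moments, strengths) for a bundle
#'
#' Computes DVPT2 transition moments for every 1- and 2-quanta state and,
#' at the GVPT2 level, projects them onto the variational states. Dipole
#' strengths are reported in 1e-40 esu^2 cm^2 and rotatory strengths in
#' 1e-44 esu^2 cm^2 when surfaces named "electric_dipole" and
#' "magnetic_dipole" are present.
#'
#' @param bundle a \code{VibData}.
#' @param resdb a \code{ResonanceDB} (may be empty).
#' @param level "VPT2", "DVPT2" or "GVPT2".
#' @param harmonicLevel use harmonic energies and zeroth-order moments.
#' @return list(table = data.frame, gvpt2 = \code{GVPT2Result} or NULL,
#'   chi = \code{ChiMatrix}).
#' @export
stickTable <- function(bundle, resdb, level = c("GVPT2", "DVPT2", "VPT2"),
                       harmonicLevel = FALSE) {
  level <- match.arg(level)
  harm <- bundle@harmonic
  n <- length(harm@omega)
  cst <- spectroConstants()
  chiMode <- if (level == "VPT2") "VPT2" else "DVPT2"
  rdb <- if (level == "VPT2") emptyResonanceDB() else resdb
  chiMat <- computeChi(harm, bundle@field, rdb, mode = chiMode)
  energies <- stateSpaceEnergies(chiMat)
  labels <- names(energies)
  states <- lapply(labels, labelToState)
  if (harmonicLevel) {
    energies <- vapply(states, function(s)
      sum(denseQuanta(s, n) * harm@omega), numeric(1))
    names(energies) <- labels
  }
  momentLevel <- if (harmonicLevel) "harmonic" else "VPT2"
  moments <- lapply(bundle@properties, function(surf) {
    m <- do.call(rbind, lapply(states, function(s)
      transitionMoment(s, harm, bundle@field, surf,
                       resdb = if (level == "VPT2") NULL else rdb,
                       level = momentLevel)$value))
    rownames(m) <- labels
    m
  })
  gv <- NULL
  if (level == "GVPT2") {
    pdb <- buildPolyads(rdb, n)
    gv <- assembleAndDiagonalize(pdb, energies)
    energies <- gv@energies
    moments <- lapply(moments, projectGvpt2, gvpt2 = gv)
  }
  tab <- data.frame(state = labels, energy = unname(energies[labels]),
                    stringsAsFactors = FALSE)
  mu <- moments[["electric_dipole"]]
  mm <- moments[["magnetic_dipole"]]
  if (!is.null(mu)) {
    tab$D <- rowSums(mu[labels, , drop = FALSE]^2) * cst$dipoleStrength
    for (c_ in seq_len(ncol(mu)))
      tab[[paste0("mu", c_)]] <- mu[labels, c_]
  }
  if (!is.null(mu) && !is.null(mm)) {
    ## R = Im(<0|mu|f><f|m|0>); with the real momentum convention the
    ## magnetic ground->f element changes sign under transposition
    tab$R <- -rowSums(mu[labels, , drop = FALSE] *
                        mm[labels, , drop = FALSE]) * cst$rotatoryStrength
  }
  list(table = tab, gvpt2 = gv, chi = chiMat)
}

emptyResonanceDB <- function() {
  new("ResonanceDB",
      table = data.frame(kind = character(0), i = integer(0), j = integer(0),
                         k = integer(0), l = integer(0), delta = numeric(0),
                         coupling = numeric(0), indexEnergy = numeric(0),
                         indexIntensity = numeric(0), trigger = character(0),
                         stringsAsFactors = FALSE),
      candidates = data.frame(), config = list(),
      coefCache = new.env(parent = emptyenv()))
}

#' Run the full pipeline
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \code{input} (VibData path) or \code{bundle} (a \code{VibData});
#'   \code{level} ("VPT2"/"DVPT2"/"GVPT2", default GVPT2);
#'   \code{resonances} (threshold configuration, default
#'   \code{\link{defaultResonanceConfig}}); \code{spectra} (list of specs:
#'   kind, shape, hwhm, shift); \code{outdir} (artifacts directory; omit to
#'   skip writing); \code{seed}.
#' @return list of artifacts: the effective config, resonance db, chi,
#'   energies, stick table, spectra, and written file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("input", "bundle", "level", "resonances", "spectra", "outdir",
             "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  level <- if (is.null(config$level)) "GVPT2" else config$level
  rescfg <- if (is.null(config$resonances)) defaultResonanceConfig() else
    utils::modifyList(defaultResonanceConfig(), config$resonances)
  bundle <- if (!is.null(config$bundle)) config$bundle else
    readVibData(config$input)
  resdb <- buildResonanceDB(bundle@harmonic, bundle@field, rescfg)
  st <- stickTable(bundle, resdb, level = level)
  specs <- config$spectra
  if (is.null(specs)) {
    specs <- list()
    if (!is.null(st$table$D))
      specs <- c(specs, list(list(kind = "IR", shape = "lorentzian",
                                  hwhm = 2, shift = 0)))
    if (!is.null(st$table$R))
      specs <- c(specs, list(list(kind = "VCD", shape = "lorentzian",
                                  hwhm = 2, shift = 0)))
  }
  spectra <- lapply(specs, function(sp) {
    bandSpectrum(st$table, kind = sp$kind,
                 shape = if (is.null(sp$shape)) "lorentzian" else sp$shape,
                 hwhm = if (is.null(sp$hwhm)) 2 else sp$hwhm,
                 shift = if (is.null(sp$shift)) 0 else sp$shift)
  })
  names(spectra) <- vapply(specs, function(sp) sp$kind, character(1))
  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(config$outdir, x)
    utils::write.csv(st$table, fp("sticks.csv"), row.names = FALSE)
    jsonlite::write_json(resdb@table, fp("resonances.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    pdb <- buildPolyads(if (level == "VPT2") emptyResonanceDB() else resdb,
                        length(bundle@harmonic@omega))
    jsonlite::write_json(lapply(pdb@polyads, function(p)
      list(states = p$states, couplings = p$couplings)),
      fp("polyads.json"), auto_unbox = TRUE, digits = NA)
    exportChi(st$chi, fp("chi.json"))
    for (k in names(spectra))
      writeBandShape(spectra[[k]], fp(paste0("spectrum_", tolower(k), ".csv")))
    eff <- config
    eff$bundle <- NULL
    eff$level <- level
    eff$resonances <- rescfg
    yaml::write_yaml(eff, fp("run.yaml"))
    files <- list.files(config$outdir, full.names = TRUE)
  }
  list(config = c(config[setdiff(names(config), c("bundle"))],
                  list(level = level, resonances = rescfg)),
       resdb = resdb, chi = st$chi, gvpt2 = st$gvpt2, table = st$table,
       spectra = spectra, files = files)
}

#' Export a chi matrix with its removed-term ledger
#'
#' @param chiMat a \code{ChiMatrix}.
#' @param path output path (.json or .csv).
#' @return \code{path}, invisibly.
#' @export
exportChi <- function(chiMat, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(chiMat@chi, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(mode = chiMat@mode, eps0 = chiMat@eps0,
                              chi = chiMat@chi,
                              removed = chiMat@removedTerms),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
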