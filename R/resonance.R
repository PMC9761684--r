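## Candidate enumeration and identification of Fermi and Darling-Dennison
## resonances. The selection is a two-step process: a fast harmonic-energy
## prefilter (|delta| < window) followed by one or two index tests, an
## energy-based one (Martin / CVPT / HRS) optionally complemented by an
## intensity-aware one based on the perturbative wave-function coefficients
## (COEF schemes). A candidate is accepted if ANY enabled test passes.

#' Enumerate Fermi-resonance candidates
#'
#' All triads (i; j <= k) with i not in {j, k} and |w_i - w_j - w_k|
#' strictly below the window. The i = j or i = k triads are excluded: they
#' would require w_k ~ 0.
#'
#' @param omega harmonic wavenumbers (cm-1).
#' @param window prefilter width, cm-1 (use \code{Inf} for pure counting).
#' @return data.frame with columns i, j, k, delta (w_i - w_j - w_k), kind
#'   (FERMI_I when j == k, else FERMI_II), ordered by i, j, k.
#' @export
enumerateFermiCandidates <- function(omega, window) {
  stopifnot(window > 0)
  n <- length(omega)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0),
                               k = integer(0), delta = numeric(0),
                               kind = character(0)))
  jj <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  kk <- unlist(lapply(seq_len(n), function(j) j:n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- jj != i & kk != i
    d <- omega[i] - omega[jj[sel]] - omega[kk[sel]]
    keep <- abs(d) < window
    out[[i]] <- data.frame(i = rep(i, sum(keep)), j = jj[sel][keep],
                           k = kk[sel][keep], delta = d[keep])
  }
  res <- do.call(rbind, out)
  res$kind <- ifelse(res$j == res$k, "FERMI_I", "FERMI_II")
  res[order(res$i, res$j, res$k), , drop = FALSE]
}

twoQuantaStates <- function(n) {
  data.frame(a = rep(seq_len(n), times = n - seq_len(n) + 1L),
             b = unlist(lapply(seq_len(n), function(a) a:n)))
}

#' Enumerate Darling-Dennison candidates
#'
#' \code{DD11}: unordered pairs of distinct fundamentals. \code{DD22}:
#' unordered pairs of distinct 2-quanta states; by default restricted to
#' overtone-overtone (2-2) and overtone-combination (2-11) patterns, since
#' combination-combination (11-11) couplings require off-semidiagonal
#' quartic constants unavailable from two-step differentiation. Disable the
#' restriction for counting the full pair space.
#'
#' @param omega harmonic wavenumbers (cm-1).
#' @param kind "DD11" or "DD22".
#' @param window prefilter width, cm-1.
#' @param restricted apply the 2-2/2-11 pattern restriction (DD22 only).
#' @return data.frame of candidates with harmonic gap \code{delta}.
#' @export
enumerateDDCandidates <- function(omega, kind = c("DD11", "DD22"), window,
                                  restricted = TRUE) {
  kind <- match.arg(kind)
  stopifnot(window > 0)
  n <- length(omega)
  if (kind == "DD11") {
    if (n < 2) return(data.frame(i = integer(0), j = integer(0),
                                 delta = numeric(0), kind = character(0)))
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1L):n))
    d <- omega[i] - omega[j]
    keep <- abs(d) < window
    return(data.frame(i = i[keep], j = j[keep], delta = d[keep],
                      kind = rep("DD11", sum(keep))))
  }
  st <- twoQuantaStates(n)
  m <- nrow(st)
  e <- omega[st$a] + omega[st$b]
  s <- rep(seq_len(m - 1), times = (m - 1):1)
  t <- unlist(lapply(seq_len(m - 1), function(a) (a + 1L):m))
  d <- e[s] - e[t]
  keep <- abs(d) < window
  res <- data.frame(i = st$a[s][keep], j = st$b[s][keep],
                    k = st$a[t][keep], l = st$b[t][keep], delta = d[keep])
  ov1 <- res$i == res$j
  ov2 <- res$k == res$l
  res$kind <- ifelse(ov1 & ov2, "DD22",
                     ifelse(ov1 | ov2, "DD211", "DD1111"))
  if (restricted) res <- res[res$kind != "DD1111", , drop = FALSE]
  rownames(res) <- NULL
  res
}

## 2x2 deperturbed couplings for a Fermi triad (a; b, c):
## <1_b 1_c | V3 | 1_a> = k_abc / (2 sqrt 2)   (type II, b != c)
## <2_b     | V3 | 1_a> = k_abb / 4            (type I,  b == c)
fermiCoupling <- function(phi, typeI) {
  if (typeI) phi / 4 else phi / (2 * sqrt(2))
}

#' Fermi-resonance index for one candidate under a named scheme
#'
#' \itemize{
#' \item \code{R12MART}: Martin's variational-deviation measure
#'   \eqn{W^4/\Delta^3} (cm-1), with the deperturbed 2x2 coupling
#'   \eqn{W = |\phi|/4} (type I) or \eqn{|\phi|/(2\sqrt 2)} (type II).
#' \item \code{R12CVPT}: divergence measure of the numerical contact
#'   transformation, \eqn{c\,|W/\Delta|} with \eqn{c=\sqrt 2} for overtones
#'   (type I) and 1 otherwise (dimensionless).
#' \item \code{R12WFRQ}: Martin's index weighted by the squared energy gap,
#'   \eqn{W^4/\Delta^5}, emphasizing near-degenerate states.
#' \item \code{R12COEF}: magnitude of the first-order wave-function
#'   coefficient \eqn{|W/\Delta|} (dimensionless), the quantity that enters
#'   the VPT2 transition moments directly.
#' }
#' An exactly degenerate candidate (delta = 0) with nonzero coupling is an
#' exact divergence: the index is \code{Inf} (auto-accepted downstream).
#'
#' @param delta harmonic gap w_i - w_j - w_k, cm-1.
#' @param phi cubic constant k_ijk, cm-1.
#' @param typeI logical, TRUE when j == k.
#' @param scheme one of "R12MART", "R12CVPT", "R12WFRQ", "R12COEF".
#' @param weight for R12WFRQ, power of the gap used as weight
#'   ("squared" or "linear").
#' @return nonnegative index value.
#' @export
fermiIndex <- function(delta, phi, typeI,
                       scheme = c("R12MART", "R12CVPT", "R12WFRQ", "R12COEF"),
                       weight = c("squared", "linear")) {
  scheme <- match.arg(scheme)
  weight <- match.arg(weight)
  if (phi == 0) return(0)
  W <- abs(fermiCoupling(phi, typeI))
  ad <- abs(delta)
  if (ad == 0) return(Inf)
  switch(scheme,
    R12MART = W^4 / ad^3,
    R12CVPT = (if (typeI) sqrt(2) else 1) * W / ad,
    R12WFRQ = W^4 / ad^3 / (if (weight == "squared") ad^2 else ad),
    R12COEF = W / ad
  )
}

#' Darling-Dennison index for one candidate under a named scheme
#'
#' The effective coupling is the second-order contact-transformed
#' (Van Vleck) matrix element between the two states, computed by the
#' explicit sum-over-states engine with internal Fermi-like denominators
#' regularized so the coupling is finite for any input.
#'
#' \itemize{
#' \item \code{R11HRS} / \code{R22HRS}: |coupling| in cm-1.
#' \item \code{R11WFRQ}: |coupling| divided by the squared harmonic gap.
#' \item \code{R11COEF}: |coupling / gap|, the second-order mixing
#'   coefficient (should be < 1 for a perturbative state).
#' }
#'
#' @param stateA,stateB \code{VibState}s (fundamentals for 1-1; 2-quanta
#'   states for 2-2/2-11).
#' @param harm a \code{HarmonicModel}.
#' @param field an \code{AnharmonicField}.
#' @param scheme one of "R11HRS", "R11WFRQ", "R11COEF", "R22HRS".
#' @param coupling optionally a precomputed coupling (cm-1) to avoid
#'   recomputation.
#' @return list(index =, coupling =, delta =).
#' @export
ddIndex <- function(stateA, stateB, harm, field,
                    scheme = c("R11HRS", "R11WFRQ", "R11COEF", "R22HRS"),
                    coupling = NULL) {
  scheme <- match.arg(scheme)
  omega <- harm@omega
  va <- denseQuanta(stateA, length(omega))
  vb <- denseQuanta(stateB, length(omega))
  if (is.null(coupling))
    coupling <- vanVleckCoupling(va, vb, cubicTerms(field),
                                 quarticTerms(field), omega)
  delta <- harmonicEnergy(va, omega) - harmonicEnergy(vb, omega)
  ad <- abs(delta)
  idx <- if (coupling == 0) 0
    else if (scheme %in% c("R11HRS", "R22HRS")) abs(coupling)
    else if (ad == 0) Inf
    else if (scheme == "R11WFRQ") abs(coupling) / ad^2
    else abs(coupling / delta)
  list(index = idx, coupling = coupling, delta = delta)
}

#' Default identification thresholds
#'
#' The recommended protocol: R12MART complemented by R12COEF for Fermi
#' resonances (window 200 cm-1, K = 1.0 cm-1, K_I = 0.1), R11HRS
#' complemented by R11COEF for 1-1 Darling-Dennison (window 100 cm-1,
#' K = 10 cm-1, K_I = 0.3), and R22HRS alone for 2-2/2-11 (window 100,
#' K = 20 cm-1).
#'
#' @return nested list of per-kind windows, schemes and thresholds.
#' @export
defaultResonanceConfig <- function() {
  list(
    fermi = list(window = 200, energy = list(scheme = "R12MART", K = 1.0),
                 intensity = list(scheme = "R12COEF", K = 0.1)),
    dd11 = list(window = 100, energy = list(scheme = "R11HRS", K = 10),
                intensity = list(scheme = "R11COEF", K = 0.3)),
    dd22 = list(window = 100, energy = list(scheme = "R22HRS", K = 20),
                intensity = NULL)
  )
}

knownSchemes <- list(
  fermi = c("R12MART", "R12CVPT", "R12WFRQ", "R12COEF"),
  dd11 = c("R11HRS", "R11WFRQ", "R11COEF"),
  dd22 = c("R22HRS")
)

checkScheme <- function(kind, test) {
  if (is.null(test)) return(invisible(NULL))
  if (!test$scheme %in% knownSchemes[[kind]])
    stop("unknown ", kind, " scheme '", test$scheme, "'")
  invisible(NULL)
}

#' Automatic identification of resonances
#'
#' Enumerates Fermi, 1-1 and 2-2/2-11 Darling-Dennison candidates inside
#' the configured windows, evaluates the configured energy and (optionally)
#' intensity indices, and accepts a candidate if either test passes
#' (logical OR). Exactly degenerate candidates with nonzero coupling are
#' always accepted. The result is deterministic for fixed input, and can be
#' amended with \code{\link{amendResonanceDB}}.
#'
#' @param harm a \code{HarmonicModel}.
#' @param field an \code{AnharmonicField}.
#' @param config thresholds per kind; see \code{\link{defaultResonanceConfig}}.
#' @return a \code{ResonanceDB}.
#' @export
buildResonanceDB <- function(harm, field, config = defaultResonanceConfig()) {
  omega <- harm@omega
  n <- length(omega)
  for (kind in c("fermi", "dd11", "dd22")) {
    checkScheme(kind, config[[kind]]$energy)
    checkScheme(kind, config[[kind]]$intensity)
  }
  cache <- new.env(parent = emptyenv())
  rows <- list(); cand <- list()
  addRow <- function(df) rows[[length(rows) + 1L]] <<- df
  addCand <- function(df) cand[[length(cand) + 1L]] <<- df
  evalTests <- function(idxE, idxI, cfg) {
    passE <- !is.null(cfg$energy) && !is.na(idxE) && idxE >= cfg$energy$K
    passI <- !is.null(cfg$intensity) && !is.na(idxI) && idxI >= cfg$intensity$K
    trig <- c(if (passE) cfg$energy$scheme, if (passI) cfg$intensity$scheme)
    list(accept = passE || passI, trigger = paste(trig, collapse = "+"))
  }
  ## Fermi
  cfg <- config$fermi
  fr <- enumerateFermiCandidates(omega, cfg$window)
  if (nrow(fr)) for (r in seq_len(nrow(fr))) {
    i <- fr$i[r]; j <- fr$j[r]; k <- fr$k[r]
    phi <- cubicConstant(field, i, j, k)
    typeI <- j == k
    idxE <- if (is.null(cfg$energy)) NA_real_ else
      fermiIndex(fr$delta[r], phi, typeI, cfg$energy$scheme)
    idxI <- if (is.null(cfg$intensity)) NA_real_ else
      fermiIndex(fr$delta[r], phi, typeI, cfg$intensity$scheme)
    W <- fermiCoupling(phi, typeI)
    row <- data.frame(kind = fr$kind[r], i = i, j = j, k = k, l = NA_integer_,
                      delta = fr$delta[r], coupling = W,
                      indexEnergy = if (is.na(idxE)) NA_real_ else idxE,
                      indexIntensity = if (is.na(idxI)) NA_real_ else idxI,
                      trigger = "", stringsAsFactors = FALSE)
    res <- evalTests(idxE, idxI, cfg)
    row$trigger <- res$trigger
    addCand(row)
    if (phi != 0 && res$accept) addRow(row)
  }
  ## DD couplings need the sum-over-states engine
  v3t <- cubicTerms(field); v4t <- quarticTerms(field)
  ddCoupling <- function(va, vb)
    vanVleckCoupling(va, vb, v3t, v4t, omega)
  evalDD <- function(va, vb, cfg, kindLabel, i, j, k, l) {
    coup <- ddCoupling(va, vb)
    delta <- harmonicEnergy(va, omega) - harmonicEnergy(vb, omega)
    mk <- function(test) {
      if (is.null(test)) return(NA_real_)
      ddIndex(stateFromDense(va), stateFromDense(vb), harm, field,
              scheme = test$scheme, coupling = coup)$index
    }
    idxE <- mk(cfg$energy); idxI <- mk(cfg$intensity)
    res <- evalTests(if (is.na(idxE)) -Inf else idxE,
                     idxI, cfg)
    row <- data.frame(kind = kindLabel, i = i, j = j, k = k, l = l,
                      delta = delta, coupling = coup,
                      indexEnergy = idxE, indexIntensity = idxI,
                      trigger = res$trigger, stringsAsFactors = FALSE)
    addCand(row)
    if (coup != 0 && (res$accept || delta == 0)) {
      if (coup != 0 && delta == 0 && row$trigger == "")
        row$trigger <- "degenerate"
      addRow(row)
    }
    ## cache the signed second-order mixing coefficient for
    ## pseudoeigenvectors / diagnostics
    if (kindLabel == "DD11" && delta != 0)
      assign(sprintf("c2|%d|%d", i, k), coup / delta, envir = cache)
    invisible(NULL)
  }
  cfg <- config$dd11
  dd <- enumerateDDCandidates(omega, "DD11", cfg$window)
  if (nrow(dd)) for (r in seq_len(nrow(dd))) {
    i <- dd$i[r]; j <- dd$j[r]
    evalDD(denseQuanta(vibState(i), n), denseQuanta(vibState(j), n),
           cfg, "DD11", i, NA_integer_, j, NA_integer_)
  }
  cfg <- config$dd22
  dd <- enumerateDDCandidates(omega, "DD22", cfg$window, restricted = TRUE)
  if (nrow(dd)) for (r in seq_len(nrow(dd))) {
    sA <- if (dd$i[r] == dd$j[r]) vibState(dd$i[r], 2L) else
      vibState(c(dd$i[r], dd$j[r]))
    sB <- if (dd$k[r] == dd$l[r]) vibState(dd$k[r], 2L) else
      vibState(c(dd$k[r], dd$l[r]))
    evalDD(denseQuanta(sA, n), denseQuanta(sB, n), cfg, dd$kind[r],
           dd$i[r], dd$j[r], dd$k[r], dd$l[r])
  }
  empty <- data.frame(kind = character(0), i = integer(0), j = integer(0),
                      k = integer(0), l = integer(0), delta = numeric(0),
                      coupling = numeric(0), indexEnergy = numeric(0),
                      indexIntensity = numeric(0), trigger = character(0),
                      stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows) else empty
  cands <- if (length(cand)) do.call(rbind, cand) else empty
  rownames(tab) <- rownames(cands) <- NULL
  new("ResonanceDB", table = tab, candidates = cands, config = config,
      coefCache = cache)
}

#' Amend a resonance database
#'
#' The automatically generated list can be replaced or amended: individual
#' resonances can be removed, or added with a user-supplied coupling.
#'
#' @param resdb a \code{ResonanceDB}.
#' @param remove integer vector of row numbers of \code{resdb@table} to drop.
#' @param add data.frame in the layout of \code{resdb@table} to append.
#' @return the amended \code{ResonanceDB}.
#' @export
amendResonanceDB <- function(resdb, remove = NULL, add = NULL) {
  tab <- resdb@table
  if (!is.null(remove)) tab <- tab[-remove, , drop = FALSE]
  if (!is.null(add)) {
    add$trigger <- if (is.null(add$trigger)) "user" else add$trigger
    for (col in setdiff(names(tab), names(add))) add[[col]] <- NA
    tab <- rbind(tab, add[names(tab)])
  }
  rownames(tab) <- NULL
  initialize(resdb, table = tab)
}

## ---- polyads ----

stateKeyFund <- function(i) stateLabel(vibState(i))

#' Human-readable state label ("0" ground, "1(3)", "2(5)", "1(1)+1(4)")
#' @param state a \code{VibState}.
#' @return character label.
#' @export
stateLabel <- function(state) {
  q <- state@quanta
  if (!length(q)) return("0")
  paste(sprintf("%d(%s)", q, names(q)), collapse = "+")
}

labelToState <- function(label) {
  if (label == "0") return(vibState())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\((\\d+)\\)$", parts))
  vibState(vapply(m, function(x) as.integer(x[3]), integer(1)),
           vapply(m, function(x) as.integer(x[2]), integer(1)))
}

unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  list(find = find,
       union = function(a, b) {
         ra <- find(a); rb <- find(b)
         if (ra != rb) parent[rb] <<- ra
       })
}

resonanceEdges <- function(resdb) {
  tb <- resdb@table
  if (!nrow(tb)) return(data.frame(from = character(0), to = character(0),
                                   coupling = numeric(0)))
  from <- character(nrow(tb)); to <- character(nrow(tb))
  for (r in seq_len(nrow(tb))) {
    if (tb$kind[r] %in% c("FERMI_I", "FERMI_II")) {
      from[r] <- stateLabel(vibState(tb$i[r]))
      to[r] <- if (tb$j[r] == tb$k[r]) stateLabel(vibState(tb$j[r], 2L)) else
        stateLabel(vibState(c(tb$j[r], tb$k[r])))
    } else if (tb$kind[r] == "DD11") {
      from[r] <- stateLabel(vibState(tb$i[r]))
      to[r] <- stateLabel(vibState(tb$k[r]))
    } else {
      from[r] <- if (tb$i[r] == tb$j[r]) stateLabel(vibState(tb$i[r], 2L)) else
        stateLabel(vibState(c(tb$i[r], tb$j[r])))
      to[r] <- if (tb$k[r] == tb$l[r]) stateLabel(vibState(tb$k[r], 2L)) else
        stateLabel(vibState(c(tb$k[r], tb$l[r])))
    }
  }
  data.frame(from = from, to = to, coupling = tb$coupling,
             stringsAsFactors = FALSE)
}

#' Group resonant states into polyads
#'
#' Polyads are the connected components of the graph whose vertices are the
#' 1- and 2-quanta states (dimension N + N(N+1)/2) and whose edges are the
#' accepted resonances. Each polyad carries the symmetric coupling matrix
#' used by the variational step.
#'
#' @param resdb a \code{ResonanceDB}.
#' @param nModes number of modes defining the state space.
#' @return a \code{PolyadDB}; singleton states are not stored as polyads but
#'   remain part of the state space.
#' @export
buildPolyads <- function(resdb, nModes) {
  n <- nModes
  st2 <- twoQuantaStates(n)
  keys <- c(vapply(seq_len(n), function(i) stateLabel(vibState(i)),
                   character(1)),
            vapply(seq_len(nrow(st2)), function(r) {
              if (st2$a[r] == st2$b[r]) stateLabel(vibState(st2$a[r], 2L))
              else stateLabel(vibState(c(st2$a[r], st2$b[r])))
            }, character(1)))
  edges <- resonanceEdges(resdb)
  uf <- unionFind(length(keys))
  pos <- stats::setNames(seq_along(keys), keys)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- match(edges$from[r], keys); b <- match(edges$to[r], keys)
    if (is.na(a) || is.na(b)) stop("resonance edge outside state space")
    uf$union(a, b)
  }
  roots <- vapply(seq_along(keys), uf$find, integer(1))
  polyads <- list()
  for (root in unique(roots)) {
    members <- which(roots == root)
    if (length(members) < 2) next
    mk <- keys[members]
    cm <- matrix(0, length(mk), length(mk), dimnames = list(mk, mk))
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      a <- edges$from[r]; b <- edges$to[r]
      if (a %in% mk && b %in% mk) {
        cm[a, b] <- edges$coupling[r]
        cm[b, a] <- edges$coupling[r]
      }
    }
    polyads[[length(polyads) + 1L]] <- list(states = mk, couplings = cm)
  }
  new("PolyadDB", polyads = polyads, stateSpace = keys)
}
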