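## VPT2/DVPT2 transition moments by explicit Rayleigh-Schroedinger
## perturbation theory: the initial (ground) and final wave functions are
## expanded to second order in the harmonic basis, the property operator is
## expanded to the matching order, and the bra-ket integral is collected by
## perturbation order, including the second-order normalization term. The
## deperturbed (DVPT2) variant removes every contribution whose denominator
## corresponds to an accepted resonance, which by construction yields the
## resonance-consistent form of the moment formulas.

## property operator split by perturbative order for one component:
## order 0 = equilibrium value + first derivatives, order 1 = second
## derivatives, order 2 = third derivatives (semidiagonal).
propertyTerms <- function(surface, component) {
  n <- nrow(surface@P1)
  mom <- surface@S == -1
  t0 <- list()
  if (surface@P0[component] != 0)
    t0[[length(t0) + 1L]] <- list(modes = integer(0), types = logical(0),
                                  coef = surface@s0 * surface@P0[component])
  for (i in seq_len(n)) {
    v <- surface@P1[i, component]
    if (v != 0)
      t0[[length(t0) + 1L]] <- list(modes = i, types = mom,
                                    coef = surface@s1 * v)
  }
  t1 <- list()
  if (!mom) {
    for (i in seq_len(n)) for (j in i:n) {
      v <- surface@P2[i, j, component]
      if (v != 0)
        t1[[length(t1) + 1L]] <- list(modes = c(i, j), types = c(FALSE, FALSE),
                                      coef = surface@s2 * v / (if (i == j) 2 else 1))
    }
  } else {
    ## P2[i, j] = mixed derivative d2P / dq_i dp_j: ordered product q_i p_j
    for (i in seq_len(n)) for (j in seq_len(n)) {
      v <- surface@P2[i, j, component]
      if (v != 0)
        t1[[length(t1) + 1L]] <- list(modes = c(i, j), types = c(FALSE, TRUE),
                                      coef = surface@s2 * v)
    }
  }
  t2 <- list()
  for (key in names(surface@P3)) {
    v <- surface@P3[[key]][component]
    if (v == 0) next
    idx <- keyIdx(key)
    if (!mom) {
      pows <- table(idx)
      t2[[length(t2) + 1L]] <- list(modes = idx, types = rep(FALSE, 3L),
                                    coef = surface@s3 * v /
                                      prod(factorial(as.integer(pows))))
    } else {
      ## key (i, j, k): coordinates i, j and momentum index k (last)
      qidx <- idx[1:2]
      t2[[length(t2) + 1L]] <- list(modes = idx, types = c(FALSE, FALSE, TRUE),
                                    coef = surface@s3 * v /
                                      (if (qidx[1] == qidx[2]) 2 else 1))
    }
  }
  list(t0 = t0, t1 = t1, t2 = t2)
}

## state keys that are deperturbed partners of `state` according to resdb
removedPartnerKeys <- function(state, resdb, n) {
  if (is.null(resdb) || !nrow(resdb@table)) return(character(0))
  tb <- resdb@table
  v <- denseQuanta(state, n)
  tot <- sum(v)
  keys <- character(0)
  mk <- function(...) stateKeyV(denseQuanta(vibState(...), n))
  for (r in seq_len(nrow(tb))) {
    kind <- tb$kind[r]
    if (kind %in% c("FERMI_I", "FERMI_II")) {
      fund <- denseQuanta(vibState(tb$i[r]), n)
      two <- if (tb$j[r] == tb$k[r]) denseQuanta(vibState(tb$j[r], 2L), n) else
        denseQuanta(vibState(c(tb$j[r], tb$k[r])), n)
      if (all(v == fund)) keys <- c(keys, stateKeyV(two))
      if (all(v == two)) keys <- c(keys, stateKeyV(fund))
    } else if (kind == "DD11") {
      a <- denseQuanta(vibState(tb$i[r]), n)
      b <- denseQuanta(vibState(tb$k[r]), n)
      if (all(v == a)) keys <- c(keys, stateKeyV(b))
      if (all(v == b)) keys <- c(keys, stateKeyV(a))
    } else {
      a <- if (tb$i[r] == tb$j[r]) denseQuanta(vibState(tb$i[r], 2L), n) else
        denseQuanta(vibState(c(tb$i[r], tb$j[r])), n)
      b <- if (tb$k[r] == tb$l[r]) denseQuanta(vibState(tb$k[r], 2L), n) else
        denseQuanta(vibState(c(tb$k[r], tb$l[r])), n)
      if (all(v == a)) keys <- c(keys, stateKeyV(b))
      if (all(v == b)) keys <- c(keys, stateKeyV(a))
    }
  }
  unique(keys)
}

## first- and second-order RSPT coefficients of state v (energy E relative
## harmonic), with resonant components removed and ledgered
rsptCoefficients <- function(v, omega, v3t, v4t, removedKeys = character(0),
                             singTol = 1e-6) {
  E <- harmonicEnergy(v, omega)
  selfKey <- stateKeyV(v)
  removedLog <- character(0)
  wf <- applyTerms(v, v3t)
  c1 <- numeric(0)
  for (key in names(wf)) {
    if (key == selfKey) next
    if (key %in% removedKeys) { removedLog <- c(removedLog, key); next }
    den <- E - harmonicEnergy(keyToV(key, length(omega)), omega)
    if (abs(den) < singTol)
      stop("near-singular untreated denominator between states ", selfKey,
           " and ", key, "; add the resonance to the configuration",
           call. = FALSE)
    c1[key] <- wf[[key]] / den
  }
  acc <- new.env(parent = emptyenv())
  for (key in names(c1)) {
    wft <- applyTerms(keyToV(key, length(omega)), v3t)
    for (s in names(wft)) {
      acc[[s]] <- (if (is.null(acc[[s]])) 0 else acc[[s]]) +
        wft[[s]] * c1[[key]]
    }
  }
  wf4 <- applyTerms(v, v4t)
  for (s in names(wf4))
    acc[[s]] <- (if (is.null(acc[[s]])) 0 else acc[[s]]) + wf4[[s]]
  c2 <- numeric(0)
  for (s in ls(acc)) {
    if (s == selfKey) next
    if (s %in% removedKeys) { removedLog <- c(removedLog, s); next }
    den <- E - harmonicEnergy(keyToV(s, length(omega)), omega)
    if (abs(den) < singTol)
      stop("near-singular untreated denominator between states ", selfKey,
           " and ", s, "; add the resonance to the configuration",
           call. = FALSE)
    c2[s] <- acc[[s]] / den
  }
  list(c1 = c1, c2 = c2, removed = unique(removedLog))
}

## <x| T |wf> where wf is a sparse wave function: apply T to each component
sparseElem <- function(xkey, terms, wfc, n) {
  if (!length(wfc) || !length(terms)) return(0)
  total <- 0
  for (s in names(wfc)) {
    out <- applyTerms(keyToV(s, n), terms)
    if (xkey %in% names(out)) total <- total + out[[xkey]] * wfc[[s]]
  }
  total
}

#' Anharmonic transition moment from the ground state
#'
#' Computes the VPT2 (or deperturbed/harmonic) transition moment of a
#' property to a fundamental or 2-quanta state. At the harmonic level,
#' overtones and combinations are dark unless the property carries second
#' or third derivatives.
#'
#' @param finalState a \code{VibState} with 1 or 2 total quanta.
#' @param harm a \code{HarmonicModel}.
#' @param field an \code{AnharmonicField}.
#' @param surface a \code{PropertySurface}.
#' @param resdb optional \code{ResonanceDB}; when supplied, the moment is
#'   deperturbed: every contribution whose denominator corresponds to an
#'   accepted resonance of \code{finalState} is omitted and ledgered.
#' @param level "VPT2" (full second order; equals DVPT2 with an empty
#'   resonance list) or "harmonic" (zeroth order only).
#' @return list with \code{value} (numeric, one entry per component, in the
#'   property's units), \code{removed} (state keys of deperturbed
#'   partners), \code{level}, and \code{state}.
#' @export
transitionMoment <- function(finalState, harm, field, surface, resdb = NULL,
                             level = c("VPT2", "harmonic")) {
  level <- match.arg(level)
  omega <- harm@omega
  n <- length(omega)
  vI <- integer(n)
  vF <- denseQuanta(finalState, n)
  nc <- surface@nComponents
  value <- numeric(nc)
  removed <- character(0)
  if (level == "harmonic") {
    for (c_ in seq_len(nc)) {
      pt <- propertyTerms(surface, c_)
      value[c_] <- elemTerms(vI, pt$t0, vF)
    }
    return(list(value = value, removed = removed, level = level,
                state = finalState))
  }
  v3t <- cubicTerms(field)
  v4t <- quarticTerms(field)
  remKeys <- removedPartnerKeys(finalState, resdb, n)
  coI <- rsptCoefficients(vI, omega, v3t, v4t)
  coF <- rsptCoefficients(vF, omega, v3t, v4t, removedKeys = remKeys)
  removed <- coF$removed
  normI <- sum(coI$c1^2)
  normF <- sum(coF$c1^2)
  keyI <- stateKeyV(vI)
  for (c_ in seq_len(nc)) {
    pt <- propertyTerms(surface, c_)
    M0 <- elemTerms(vI, pt$t0, vF)
    wfF0 <- applyTerms(vF, pt$t0)
    wfF1 <- applyTerms(vF, pt$t1)
    ## order 1
    M1 <- elemTerms(vI, pt$t1, vF)
    M1 <- M1 + overlapAt(wfF0, coI$c1)                 # <psiI1| t0 |F>
    M1 <- M1 + sparseElem(keyI, pt$t0, coF$c1, n)      # <I| t0 |psiF1>
    ## order 2
    M2 <- elemTerms(vI, pt$t2, vF)
    M2 <- M2 + overlapAt(wfF1, coI$c1)                 # <psiI1| t1 |F>
    M2 <- M2 + sparseElem(keyI, pt$t1, coF$c1, n)      # <I| t1 |psiF1>
    M2 <- M2 + crossElem(coI$c1, pt$t0, coF$c1, n)     # <psiI1| t0 |psiF1>
    M2 <- M2 + overlapAt(wfF0, coI$c2)                 # <psiI2| t0 |F>
    M2 <- M2 + sparseElem(keyI, pt$t0, coF$c2, n)      # <I| t0 |psiF2>
    M2 <- M2 - 0.5 * (normI + normF) * M0              # normalization
    value[c_] <- M0 + M1 + M2
  }
  list(value = value, removed = removed, level = if (length(remKeys))
    "DVPT2" else "VPT2", state = finalState)
}

overlapAt <- function(wf, coefs) {
  keys <- intersect(names(wf), names(coefs))
  if (!length(keys)) return(0)
  sum(wf[keys] * coefs[keys])
}

crossElem <- function(cI, terms, cF, n) {
  if (!length(cI) || !length(cF) || !length(terms)) return(0)
  total <- 0
  for (s in names(cF)) {
    out <- applyTerms(keyToV(s, n), terms)
    total <- total + overlapAt(out, cI) * cF[[s]]
  }
  total
}

#' Transition moment of a fundamental band
#' @inheritParams transitionMoment
#' @param i mode index.
#' @return as \code{\link{transitionMoment}}.
#' @export
tmFundamental <- function(i, harm, field, surface, resdb = NULL,
                          level = c("VPT2", "harmonic")) {
  transitionMoment(vibState(i), harm, field, surface, resdb, level)
}

#' Transition moment of a first overtone or 1+1 combination band
#' @inheritParams transitionMoment
#' @param state a \code{VibState} with exactly two quanta.
#' @return as \code{\link{transitionMoment}}.
#' @export
tmTwoQuanta <- function(state, harm, field, surface, resdb = NULL,
                        level = c("VPT2", "harmonic")) {
  if (sum(state@quanta) != 2L) stop("state must carry exactly 2 quanta")
  transitionMoment(state, harm, field, surface, resdb, level)
}

#' Project deperturbed moments onto the variational (GVPT2) states
#'
#' Each variational level's moment is the eigenvector-weighted combination
#' of the DVPT2 moments of its polyad; for orthonormal eigenvectors the sum
#' of squared moment norms over a polyad is conserved. States outside any
#' polyad pass through unchanged.
#'
#' @param moments matrix of DVPT2 moments: rows named by state label (see
#'   \code{\link{stateLabel}}), one column per component.
#' @param gvpt2 a \code{GVPT2Result}.
#' @return matrix of GVPT2 moments with rows renamed to the dominant DVPT2
#'   label of each variational level.
#' @export
projectGvpt2 <- function(moments, gvpt2) {
  out <- moments
  for (b in gvpt2@blocks) {
    miss <- setdiff(b$states, rownames(moments))
    if (length(miss)) stop("missing moments for polyad state ", miss[1])
    sub <- moments[b$states, , drop = FALSE]
    proj <- t(b$vectors) %*% sub # one row per variational level, ascending
    lab <- b$assignment$state
    if (!any(duplicated(lab))) out[lab, ] <- proj
    else out[b$states, ] <- proj # heavy mixing: keep level order
  }
  out
}

#' Cartesian pseudoeigenvector of a VPT2 state
#'
#' Builds an effective Cartesian displacement for a perturbed state from
#' the columns of the normal-mode matrix weighted by the perturbative
#' wave-function coefficients: for a fundamental, the unit coefficient on
#' its own mode plus the second-order (Darling-Dennison-type) coefficients
#' on the other fundamentals; for a 2-quanta state, the first-order
#' (Fermi-type) coefficients on the fundamentals. Coefficients belonging to
#' accepted resonances are excluded; coefficients already computed during
#' resonance analysis are reused from the cache.
#'
#' @param state a \code{VibState} (1 or 2 quanta).
#' @param harm a \code{HarmonicModel}.
#' @param field an \code{AnharmonicField}.
#' @param resdb optional \code{ResonanceDB} (resonant exclusion + cache).
#' @param useCache reuse coefficients cached in \code{resdb}.
#' @return list(cartesian = 3*nAtoms vector, coefficients = named numeric
#'   by mode index).
#' @export
pseudoEigenvector <- function(state, harm, field, resdb = NULL,
                              useCache = TRUE) {
  omega <- harm@omega
  n <- length(omega)
  v <- denseQuanta(state, n)
  tot <- sum(v)
  coefs <- numeric(n)
  v3t <- cubicTerms(field)
  v4t <- quarticTerms(field)
  remKeys <- removedPartnerKeys(state, resdb, n)
  if (tot == 1L) {
    i <- which(v == 1L)
    coefs[i] <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      if (stateKeyV(denseQuanta(vibState(j), n)) %in% remKeys) next
      cc <- NULL
      if (useCache && !is.null(resdb)) {
        key <- sprintf("c2|%d|%d", min(i, j), max(i, j))
        if (exists(key, envir = resdb@coefCache, inherits = FALSE)) {
          cc <- get(key, envir = resdb@coefCache)
          if (i > j) cc <- -cc # cached as coupling/(w_min - w_max)
        }
      }
      if (is.null(cc)) {
        K <- vanVleckCoupling(denseQuanta(vibState(i), n),
                              denseQuanta(vibState(j), n), v3t, v4t, omega)
        d <- omega[i] - omega[j]
        cc <- if (d == 0 || K == 0) 0 else K / d
      }
      coefs[j] <- cc
    }
  } else if (tot == 2L) {
    E <- harmonicEnergy(v, omega)
    wf <- applyTerms(v, v3t)
    for (m in seq_len(n)) {
      key <- stateKeyV(denseQuanta(vibState(m), n))
      if (!key %in% names(wf)) next
      if (key %in% remKeys) next
      d <- E - omega[m]
      coefs[m] <- if (d == 0) 0 else wf[[key]] / d
    }
  } else stop("pseudoeigenvectors are defined for 1- and 2-quanta states")
  list(cartesian = as.numeric(harm@L %*% coefs),
       coefficients = stats::setNames(coefs, seq_len(n)))
}
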