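## Sparse ladder-operator algebra over the harmonic-oscillator product basis.
## States are dense integer quanta vectors (the machinery is only used on
## small mode counts); sparse wave functions are named numeric vectors keyed
## by the state string. Operators are lists of monomial terms
## list(modes=, pows=, types=, coef=) with q = (b' + b)/sqrt(2) and, for
## momentum-type property factors, p = (b' - b)/sqrt(2) in the real
## convention (the overall i of a momentum operator is carried implicitly).

stateKeyV <- function(v) paste(v, collapse = ".")

keyToV <- function(key, n) {
  v <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
  stopifnot(length(v) == n)
  v
}

denseQuanta <- function(state, n) {
  v <- integer(n)
  q <- state@quanta
  if (length(q)) v[as.integer(names(q))] <- q
  v
}

stateFromDense <- function(v) {
  idx <- which(v > 0L)
  vibState(idx, v[idx])
}

## Build monomial term lists from an AnharmonicField. A term is
## list(modes =, types =, coef =): an ordered product of single-power
## factors (types: FALSE = q, TRUE = p), applied to the ket from the
## rightmost factor. coefficient = constant / prod(factorial(powers)), so
## that V = (1/6) sum_ijk k_ijk q_i q_j q_k over the full tensor equals the
## sum over sorted tuples.
fieldTerms <- function(consts) {
  keys <- names(consts)
  lapply(keys, function(key) {
    idx <- keyIdx(key)
    pows <- table(idx)
    list(modes = idx, types = rep(FALSE, length(idx)),
         coef = unname(consts[[key]]) / prod(factorial(as.integer(pows))))
  })
}

cubicTerms <- function(field) fieldTerms(field@cubic)

quarticTerms <- function(field) fieldTerms(field@quartic)

## Apply a list of monomial terms to a dense state; returns a sparse wave
## function (named numeric by state key). nmax (optional) truncates.
applyTerms <- function(v, terms, nmax = Inf) {
  acc <- new.env(parent = emptyenv())
  for (tm in terms) {
    if (tm$coef == 0) next
    parts <- list(list(v = v, amp = tm$coef))
    nf <- length(tm$modes)
    for (f in rev(seq_len(nf))) {
      mode <- tm$modes[f]; mom <- tm$types[f]
      nxt <- vector("list", 2L * length(parts)); nn <- 0L
      for (pp in parts) {
        m <- pp$v[mode]
        if (m + 1L <= nmax) {
          nv <- pp$v; nv[mode] <- m + 1L
          nn <- nn + 1L
          nxt[[nn]] <- list(v = nv, amp = pp$amp * sqrt((m + 1) / 2))
        }
        if (m > 0L) {
          nv <- pp$v; nv[mode] <- m - 1L
          nn <- nn + 1L
          nxt[[nn]] <- list(v = nv,
                            amp = pp$amp * (if (mom) -1 else 1) * sqrt(m / 2))
        }
      }
      parts <- nxt[seq_len(nn)]
    }
    for (pp in parts) {
      key <- stateKeyV(pp$v)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pp$amp
    }
  }
  keys <- ls(acc)
  out <- vapply(keys, function(k) acc[[k]], numeric(1))
  out[abs(out) > 1e-14]
}

## <bra| terms |ket> for dense states
elemTerms <- function(bra, terms, ket) {
  wf <- applyTerms(ket, terms)
  key <- stateKeyV(bra)
  if (key %in% names(wf)) unname(wf[[key]]) else 0
}

harmonicEnergy <- function(v, omega) sum(v * omega)

## Smooth degeneracy-corrected replacement for a resonant term W^2/D.
## Matches W^2/D exponentially fast away from resonance and passes
## continuously through D = 0 (see the methods vignette).
hdcptTerm <- function(D, W) {
  W2 <- W * W
  if (W2 == 0) return(0)
  if (abs(D) > 12 * abs(W)) return(W2 / D)
  x <- D * D / (4 * W2)
  lam <- 1 - exp(-x * x)
  plain <- if (D == 0) 0 else lam * W2 / D
  plain + (1 - lam) * W2 * D / (D * D + 4 * W2)
}

## Regularized reciprocal used inside second-order sums: behaves as 1/D with
## the scale of the numerator magnitude w2 >= 0 controlling the switch.
hdcptReciprocal <- function(D, w2) {
  if (w2 <= 0) return(if (D == 0) 0 else 1 / D)
  hdcptTerm(D, sqrt(w2)) / w2
}

## Second-order Van Vleck effective coupling <a|Heff|b> between two harmonic
## states (dense vectors) outside the trivial diagonal:
##   <a|V4|b> + 1/2 sum_s <a|V3|s><s|V3|b> [1/(Ea-Es) + 1/(Eb-Es)]
## with s excluded from the model space and internal near-resonant
## denominators regularized (HDCPT2-style) so the coupling is finite.
vanVleckCoupling <- function(va, vb, v3terms, v4terms, omega,
                             excludeKeys = character(0)) {
  direct <- elemTerms(va, v4terms, vb)
  wfa <- applyTerms(va, v3terms)
  wfb <- applyTerms(vb, v3terms)
  keys <- intersect(names(wfa), names(wfb))
  keys <- setdiff(keys, c(stateKeyV(va), stateKeyV(vb), excludeKeys))
  Ea <- harmonicEnergy(va, omega)
  Eb <- harmonicEnergy(vb, omega)
  second <- 0
  for (key in keys) {
    vs <- keyToV(key, length(omega))
    Es <- harmonicEnergy(vs, omega)
    w <- wfa[[key]] * wfb[[key]]
    second <- second + 0.5 * w *
      (hdcptReciprocal(Ea - Es, abs(w)) + hdcptReciprocal(Eb - Es, abs(w)))
  }
  direct + second
}
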