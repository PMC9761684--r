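## The GVPT2 variational step: per-polyad matrices with deperturbed (DVPT2)
## energies on the diagonal and the Fermi / Darling-Dennison couplings
## off-diagonal, diagonalized block by block.

#' Assemble and diagonalize the per-polyad variational matrices
#'
#' @param polyaddb a \code{PolyadDB}.
#' @param dvpt2Energies named numeric: DVPT2 energy (cm-1, relative to the
#'   ground state) per state key; must cover every polyad state.
#' @param global diagonalize one global sparse matrix instead of per-polyad
#'   blocks (cross-validation only; equivalent by construction).
#' @return a \code{GVPT2Result}. Eigenvalues are ascending per polyad;
#'   eigenvector phases are fixed by making the largest-magnitude component
#'   positive; singleton states pass through unchanged.
#' @export
assembleAndDiagonalize <- function(polyaddb, dvpt2Energies, global = FALSE) {
  energies <- dvpt2Energies
  blocks <- list()
  if (global) {
    keys <- polyaddb@stateSpace
    miss <- setdiff(unlist(lapply(polyaddb@polyads, `[[`, "states")), names(energies))
    if (length(miss)) stop("missing DVPT2 energy for state ", miss[1])
    H <- diag(energies[keys], length(keys))
    dimnames(H) <- list(keys, keys)
    for (p in polyaddb@polyads)
      H[p$states, p$states] <- H[p$states, p$states] + p$couplings
    eig <- eigen(H, symmetric = TRUE)
    ## report as a single block
    o <- order(eig$values)
    vec <- eig$vectors[, o, drop = FALSE]
    blocks[[1]] <- list(states = keys, matrix = H,
                        values = eig$values[o], vectors = vec)
    out <- stats::setNames(eig$values[o], keys[apply(vec^2, 2, which.max)])
    return(new("GVPT2Result", blocks = blocks,
               energies = out, dvpt2 = energies))
  }
  gv <- energies
  for (p in polyaddb@polyads) {
    miss <- setdiff(p$states, names(energies))
    if (length(miss)) stop("missing DVPT2 energy for state ", miss[1])
    cm <- p$couplings
    if (max(abs(cm - t(cm))) > 1e-10) stop("non-symmetric coupling matrix")
    H <- cm
    diag(H) <- energies[p$states]
    eig <- eigen(H, symmetric = TRUE)
    o <- order(eig$values)
    vals <- eig$values[o]
    vecs <- eig$vectors[, o, drop = FALSE]
    for (c_ in seq_len(ncol(vecs))) {
      m <- which.max(abs(vecs[, c_]))
      if (vecs[m, c_] < 0) vecs[, c_] <- -vecs[, c_]
    }
    rownames(vecs) <- p$states
    blocks[[length(blocks) + 1L]] <-
      list(states = p$states, matrix = H, values = vals, vectors = vecs,
           assignment = assignBlock(p$states, vals, vecs,
                                    energies[p$states]))
    ## report each GVPT2 level under its dominant DVPT2 label
    asg <- blocks[[length(blocks)]]$assignment
    gv[asg$state] <- vals
  }
  new("GVPT2Result", blocks = blocks, energies = gv, dvpt2 = energies)
}

assignBlock <- function(states, vals, vecs, diagE) {
  rows <- lapply(seq_along(vals), function(c_) {
    w <- vecs[, c_]^2
    best <- max(w)
    cand <- which(abs(w - best) < 1e-12)
    tie <- length(cand) > 1
    pick <- cand[which.min(diagE[cand])] # tie-break toward lower DVPT2 energy
    data.frame(level = c_, energy = vals[c_], state = states[pick],
               overlap = w[pick], tie = tie)
  })
  do.call(rbind, rows)
}

#' Assignment of GVPT2 levels to DVPT2 basis states
#'
#' Each variational level is labeled by the basis state with the largest
#' squared eigenvector component; the overlap fraction is reported and ties
#' are broken toward the lower-energy basis state (flagged).
#'
#' @param result a \code{GVPT2Result}.
#' @return data.frame with one row per variational level in coupled blocks.
#' @export
assignStates <- function(result) {
  if (!length(result@blocks))
    return(data.frame(level = integer(0), energy = numeric(0),
                      state = character(0), overlap = numeric(0),
                      tie = logical(0)))
  out <- do.call(rbind, lapply(result@blocks, `[[`, "assignment"))
  rownames(out) <- NULL
  out
}
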