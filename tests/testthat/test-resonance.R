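test_that("Fermi candidate enumeration matches the closed form", {
  expect_equal(nrow(enumerateFermiCandidates(1000, Inf)), 0)
  for (n in c(2, 3, 5, 12, 30)) {
    w <- seq(300, by = 97, length.out = n)
    got <- nrow(enumerateFermiCandidates(w, Inf))
    expect_equal(got, n * (choose(n - 1, 2) + (n - 1)))
  }
  ## constructed window case: exactly one triad inside the window
  cand <- enumerateFermiCandidates(c(2000, 995, 1010), 10)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$i, 1)
  expect_equal(cand$j, 2)
  expect_equal(cand$k, 3)
  expect_equal(cand$delta, -5)
})

test_that("Darling-Dennison candidate counts match the closed forms", {
  for (n in c(2, 5, 12, 30)) {
    w <- seq(300, by = 53, length.out = n)
    expect_equal(nrow(enumerateDDCandidates(w, "DD11", Inf)), choose(n, 2))
    m <- n * (n + 1) / 2
    expect_equal(nrow(enumerateDDCandidates(w, "DD22", Inf,
                                            restricted = FALSE)),
                 choose(m, 2))
    ## restricted set excludes combination-combination pairs
    restr <- enumerateDDCandidates(w, "DD22", Inf)
    expect_true(all(restr$i == restr$j | restr$k == restr$l))
  }
  expect_equal(nrow(enumerateDDCandidates(c(500, 700), "DD11", Inf)), 1)
})

test_that("Fermi indices: zero coupling, degeneracy, printed Martin values", {
  for (s in c("R12MART", "R12CVPT", "R12WFRQ", "R12COEF"))
    expect_equal(fermiIndex(10, 0, TRUE, s), 0)
  expect_equal(fermiIndex(0, 5, FALSE, "R12MART"), Inf)
  ## methyloxirane type-I resonance: gas-phase inputs give ~0.8 cm-1,
  ## neat-liquid inputs several hundred
  gas <- fermiIndex(17.5, 33, TRUE, "R12MART")
  liq <- fermiIndex(2.6, 38, TRUE, "R12MART")
  expect_equal(gas, (33 / 4)^4 / 17.5^3)
  expect_lt(abs(gas - 0.8), 0.1)
  expect_gt(liq / gas, 500)
})

test_that("indices are monotone in |coupling| and in |gap|", {
  phis <- seq(2, 40, by = 2)
  deltas <- seq(0.5, 60, by = 1.5)
  for (s in c("R12MART", "R12CVPT", "R12WFRQ", "R12COEF")) {
    atFixedDelta <- vapply(phis, fermiIndex, numeric(1), delta = 12,
                           typeI = FALSE, scheme = s)
    expect_true(all(diff(atFixedDelta) >= 0))
    atFixedPhi <- vapply(deltas, fermiIndex, numeric(1), phi = 25,
                         typeI = TRUE, scheme = s)
    expect_true(all(diff(atFixedPhi) <= 0))
  }
})

test_that("R12COEF equals the first-order mixing coefficient (oracle)", {
  b <- mkBundle(c(700, 710, 1435), cubic = cubicDf(1, 2, 3, 25))
  idx <- fermiIndex(1435 - 1410, 25, FALSE, "R12COEF")
  lam <- 1e-3
  orc <- variationalOracle(b, nmax = 8, lambda = lam,
                           convergenceCheck = FALSE)
  iF <- gvpt2:::oracleLevelIndex(orc, vibState(3))
  rF <- match(gvpt2:::stateKeyV(c(0L, 0L, 1L)), orc$keys)
  rC <- match(gvpt2:::stateKeyV(c(1L, 1L, 0L)), orc$keys)
  numeric1 <- abs(orc$vectors[rC, iF] / orc$vectors[rF, iF]) / lam
  expect_equal(numeric1, idx, tolerance = 1e-3)
})

test_that("DD indices vanish for uncoupled modes and match the oracle limit", {
  b0 <- mkBundle(c(1000, 1004))
  for (s in c("R11HRS", "R11WFRQ", "R11COEF"))
    expect_equal(ddIndex(vibState(1), vibState(2), b0@harmonic, b0@field,
                         s)$index, 0)
  b <- mkBundle(c(1000, 1004.5),
                cubic = cubicDf(1, 1, 2, 12, 1, 2, 2, -9),
                quartic = quarticDf(1, 1, 1, 1, 6, 1, 1, 1, 2, 24,
                                    1, 1, 2, 2, 4))
  dd <- ddIndex(vibState(1), vibState(2), b@harmonic, b@field, "R11COEF")
  lam <- 0.02
  orc <- variationalOracle(b, nmax = 12, lambda = lam,
                           convergenceCheck = FALSE)
  i1 <- gvpt2:::oracleLevelIndex(orc, vibState(1))
  r1 <- match(gvpt2:::stateKeyV(c(1L, 0L)), orc$keys)
  r2 <- match(gvpt2:::stateKeyV(c(0L, 1L)), orc$keys)
  mix <- abs(orc$vectors[r2, i1] / orc$vectors[r1, i1]) / lam^2
  expect_equal(mix, dd$index, tolerance = 1e-3)
  ## perturbative sanity bound on the mixing coefficient
  expect_lt(dd$index, 1)
})

test_that("acceptance is the OR of the energy and intensity tests", {
  b <- fermiDyadBundle()
  cfg <- defaultResonanceConfig()
  ## infinite thresholds reject everything
  cfgInf <- cfg
  cfgInf$fermi$energy$K <- Inf
  cfgInf$fermi$intensity <- NULL
  cfgInf$dd11$energy$K <- Inf
  cfgInf$dd11$intensity <- NULL
  cfgInf$dd22$energy$K <- Inf
  expect_equal(nrow(resonanceTable(buildResonanceDB(b@harmonic, b@field,
                                                    cfgInf))), 0)
  ## strong type-I resonance accepted by Martin alone (index >> 1)
  cfgE <- cfg
  cfgE$fermi$intensity <- NULL
  tabE <- resonanceTable(buildResonanceDB(b@harmonic, b@field, cfgE))
  expect_equal(nrow(tabE), 1)
  expect_gt(tabE$indexEnergy, 400)
  ## weak coupling between very close states: rejected by Martin,
  ## caught by the wave-function-coefficient test
  bw <- mkBundle(c(700, 710, 1411.2), cubic = cubicDf(1, 2, 3, 3))
  expect_lt(fermiIndex(1411.2 - 1410, 3, FALSE, "R12MART"), 1)
  expect_gt(fermiIndex(1411.2 - 1410, 3, FALSE, "R12COEF"), 0.1)
  tabEonly <- resonanceTable(buildResonanceDB(bw@harmonic, bw@field, cfgE))
  expect_equal(nrow(tabEonly), 0)
  tabBoth <- resonanceTable(buildResonanceDB(bw@harmonic, bw@field, cfg))
  expect_equal(nrow(tabBoth), 1)
  expect_equal(tabBoth$trigger, "R12COEF")
  ## OR-acceptance: dual-test set contains each single-test set
  seenBoth <- with(tabBoth, paste(kind, i, j, k))
  expect_true(all(with(tabEonly, paste(kind, i, j, k)) %in% seenBoth))
  expect_error(buildResonanceDB(b@harmonic, b@field,
                                list(fermi = list(window = 200,
                                                  energy = list(scheme = "NOPE",
                                                                K = 1)))),
               "unknown")
})

test_that("exact degeneracy short-circuits to acceptance", {
  b <- mkBundle(c(800, 1600.0), cubic = cubicDf(1, 1, 2, 1e-3))
  ## Martin index is Inf at Delta = 0 whatever the threshold
  tab <- resonanceTable(buildResonanceDB(b@harmonic, b@field))
  expect_equal(nrow(tab), 1)
})

test_that("polyads are the connected components of the resonance graph", {
  empty <- buildPolyads(gvpt2:::emptyResonanceDB(), 4)
  expect_length(polyadList(empty), 0)
  expect_length(empty@stateSpace, 4 + 10)
  ## chain A-B, B-C plus pair D-E
  tab <- data.frame(kind = c("DD11", "DD11", "DD11"),
                    i = c(1, 2, 3), j = NA, k = c(2, 3, 4), l = NA,
                    delta = 0.1, coupling = 5,
                    indexEnergy = 1, indexIntensity = 1, trigger = "user")
  rdb <- gvpt2:::emptyResonanceDB()
  rdb <- amendResonanceDB(rdb, add = tab[1:2, ])
  rdb2 <- amendResonanceDB(rdb, add = data.frame(
    kind = "FERMI_I", i = 5, j = 6, k = 6, l = NA, delta = 1, coupling = 10,
    indexEnergy = 1, indexIntensity = 1, trigger = "user"))
  pdb <- buildPolyads(rdb2, 6)
  sizes <- sort(vapply(polyadList(pdb), function(p) length(p$states),
                       integer(1)))
  expect_equal(sizes, c(2L, 3L))
  ## disjoint cover
  members <- unlist(lapply(polyadList(pdb), `[[`, "states"))
  expect_false(any(duplicated(members)))
  expect_true(all(members %in% pdb@stateSpace))
})

test_that("polyad partition agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:5) {
    n <- 6
    nEdge <- sample(2:8, 1)
    add <- data.frame(kind = "DD11",
                      i = sample(n, nEdge, replace = TRUE), j = NA,
                      k = sample(n, nEdge, replace = TRUE), l = NA,
                      delta = 0.1, coupling = 1, indexEnergy = 1,
                      indexIntensity = 1, trigger = "user")
    add <- add[add$i != add$k, , drop = FALSE]
    if (!nrow(add)) next
    rdb <- amendResonanceDB(gvpt2:::emptyResonanceDB(), add = add)
    pdb <- buildPolyads(rdb, n)
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("1(", add$i, ")"),
                 to = paste0("1(", add$k, ")")), directed = FALSE)
    comp <- igraph::components(g)
    ref <- sort(table(comp$membership))
    got <- sort(vapply(polyadList(pdb), function(p) length(p$states),
                       integer(1)))
    expect_equal(as.integer(ref[ref > 1]), as.integer(got[got > 1]))
  }
})

test_that("user amendments can add and remove resonances", {
  b <- fermiDyadBundle()
  rdb <- buildResonanceDB(b@harmonic, b@field)
  expect_equal(nrow(resonanceTable(rdb)), 1)
  rdb2 <- amendResonanceDB(rdb, remove = 1)
  expect_equal(nrow(resonanceTable(rdb2)), 0)
  rdb3 <- amendResonanceDB(rdb2, add = data.frame(
    kind = "DD11", i = 1, j = NA, k = 2, l = NA, delta = -800,
    coupling = 2, indexEnergy = NA, indexIntensity = NA))
  expect_equal(resonanceTable(rdb3)$trigger, "user")
})
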