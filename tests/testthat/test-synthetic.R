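test_that("generation is reproducible and planted gaps are exact", {
  pl <- resonancePlan(6, planted = list(list(kind = "FERMI_I", delta = 2.6,
                                             coupling = 38)), seed = 42)
  g1 <- generateBundle(pl)
  g2 <- generateBundle(pl)
  expect_identical(g1, g2)
  m <- g1$manifest
  w <- harmonicWavenumbers(g1$bundle)
  expect_equal(w[m$i] - 2 * w[m$j], 2.6, tolerance = 1e-9)
  expect_equal(cubicConstant(g1$bundle@field, m$i, m$j, m$k), 38)
  ## the planted triad is the top-ranked Fermi candidate
  rdb <- buildResonanceDB(g1$bundle@harmonic, g1$bundle@field)
  cand <- rdb@candidates
  fr <- cand[cand$kind %in% c("FERMI_I", "FERMI_II"), ]
  top <- fr[which.max(fr$indexEnergy), ]
  expect_equal(c(top$i, top$j, top$k), c(m$i, m$j, m$k))
})

test_that("zero-coupling bundles yield an empty resonance db", {
  pl <- resonancePlan(6, seed = 7, cubicScale = 0, quarticScale = 0,
                      backgroundDensity = 0)
  g <- generateBundle(pl)
  rdb <- buildResonanceDB(g$bundle@harmonic, g$bundle@field)
  expect_equal(nrow(resonanceTable(rdb)), 0)
})

test_that("infeasible plans are rejected", {
  expect_error(resonancePlan(2, planted = list(
    list(kind = "FERMI_II", delta = 1, coupling = 10))), "infeasible")
  expect_error(resonancePlan(3, planted = list(list(kind = "BOGUS"))),
               "unknown")
})

test_that("the oracle reproduces harmonic energies exactly", {
  b <- mkBundle(c(700, 1100))
  orc <- variationalOracle(b, nmax = 8)
  expect_equal(oracleEnergy(orc, vibState(1)), 700, tolerance = 1e-8)
  expect_equal(oracleEnergy(orc, vibState(c(1, 2))), 1800, tolerance = 1e-8)
  expect_equal(orc$ground, 900, tolerance = 1e-8)
})

test_that("the oracle flags an unconverged basis", {
  b <- mkBundle(1000, cubic = cubicDf(1, 1, 1, 300))
  expect_error(variationalOracle(b, nmax = 6), "not converged")
})

test_that("VPT2 error vanishes faster than second order in the coupling", {
  b <- mkBundle(c(820, 1600), cubic = cubicDf(1, 1, 2, 30),
                quartic = quarticDf(1, 1, 2, 2, 6))
  lams <- c(0.4, 0.2, 0.1)
  errs <- vapply(lams, function(lam) {
    f <- b@field
    f@cubic <- f@cubic * lam
    f@quartic <- f@quartic * lam^2
    chi <- computeChi(b@harmonic, f, mode = "VPT2")
    orc <- variationalOracle(
      new("VibData", harmonic = b@harmonic, field = f,
          properties = list()), nmax = 12)
    max(abs(stateEnergy(chi, vibState(1)) - oracleEnergy(orc, vibState(1))),
        abs(stateEnergy(chi, vibState(2)) - oracleEnergy(orc, vibState(2))))
  }, numeric(1))
  slope <- coef(stats::lm(log(errs) ~ log(lams)))[2]
  expect_gt(unname(slope), 2.5)
})

test_that("GVPT2 beats plain VPT2 on a strong Fermi dyad", {
  b <- fermiDyadBundle(delta = 2.6, phi = 38)
  orc <- variationalOracle(b, nmax = 16)
  chiV <- computeChi(b@harmonic, b@field, mode = "VPT2")
  rdb <- buildResonanceDB(b@harmonic, b@field)
  chiD <- computeChi(b@harmonic, b@field, rdb, mode = "DVPT2")
  gv <- assembleAndDiagonalize(buildPolyads(rdb, 2),
                               stateSpaceEnergies(chiD))
  for (lab in c("1(2)", "2(1)")) {
    s <- gvpt2:::labelToState(lab)
    ref <- oracleEnergy(orc, s)
    errV <- abs(stateEnergy(chiV, s) - ref)
    errG <- abs(gvpt2Energies(gv)[lab] - ref)
    expect_lt(unname(errG), unname(errV))
  }
})

test_that("planted resonances above twice the threshold are always detected", {
  cfg <- defaultResonanceConfig()
  detected <- 0L; eligible <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    pl <- resonancePlan(6, planted = list(
      list(kind = "FERMI_I", delta = stats::runif(1, 1, 8), coupling = 35),
      list(kind = "DD11", delta = stats::runif(1, 2, 6), coupling = 25)),
      seed = seed)
    g <- generateBundle(pl)
    rdb <- buildResonanceDB(g$bundle@harmonic, g$bundle@field, cfg)
    tab <- resonanceTable(rdb)
    for (r in seq_len(nrow(g$manifest))) {
      m <- g$manifest[r, ]
      if (m$kind == "FERMI_I") {
        idx <- fermiIndex(m$delta, m$coupling, TRUE, cfg$fermi$energy$scheme)
        if (idx < 2 * cfg$fermi$energy$K) next
        eligible <- eligible + 1L
        hit <- any(tab$kind == "FERMI_I" & tab$i == m$i & tab$j == m$j)
      } else {
        dd <- ddIndex(vibState(m$i), vibState(m$j), g$bundle@harmonic,
                      g$bundle@field, cfg$dd11$energy$scheme)
        if (dd$index < 2 * cfg$dd11$energy$K) next
        eligible <- eligible + 1L
        hit <- any(tab$kind == "DD11" & tab$i == m$i & tab$k == m$j)
      }
      if (hit) detected <- detected + 1L
    }
  }
  expect_gt(eligible, 0L)
  expect_equal(detected, eligible)
})

test_that("the shipped synthetic fixture matches its manifest", {
  path <- system.file("extdata", "synthetic_planted_bundle.json",
                      package = "gvpt2")
  man <- jsonlite::read_json(system.file("extdata",
                                         "synthetic_planted_manifest.json",
                                         package = "gvpt2"),
                             simplifyVector = TRUE)
  b <- readVibData(path)
  expect_equal(nModes(b), man$plan$nModes)
  tab <- resonanceTable(buildResonanceDB(b@harmonic, b@field))
  for (r in seq_len(nrow(man$planted))) {
    m <- man$planted[r, ]
    if (m$kind == "FERMI_I")
      expect_true(any(tab$kind == "FERMI_I" & tab$i == m$i & tab$j == m$j))
    if (m$kind == "DD11")
      expect_true(any(tab$kind == "DD11" & tab$i == m$i & tab$k == m$j))
  }
  ## regeneration from the recorded plan reproduces the file exactly
  plan <- do.call(resonancePlan, c(man$plan[c("nModes", "omegaRange",
                                              "minSpacing", "cubicScale",
                                              "quarticScale",
                                              "backgroundDensity",
                                              "propertyScale", "seed")],
                                   list(planted = list(
                                     list(kind = "FERMI_I", delta = 2.6,
                                          coupling = 38),
                                     list(kind = "DD11", delta = 4.5,
                                          coupling = 20)))))
  g <- generateBundle(plan)
  tmp <- tempfile(fileext = ".json")
  writeVibData(g$bundle, tmp)
  expect_identical(readLines(tmp), readLines(path))
})
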