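test_that("double-harmonic limits of the transition moments", {
  surf <- scalarSurface(2, P0 = 0.3, P1 = c(0.05, -0.02))
  b <- mkBundle(c(900, 1500), props = list(electric_dipole = surf))
  ## fundamental: s1 * P_i * <0|q|1> = P_i / sqrt(2)
  m <- tmFundamental(1, b@harmonic, b@field, surf)
  expect_equal(m$value, 0.05 / sqrt(2))
  ## overtones and combinations are dark at this level
  expect_equal(tmTwoQuanta(vibState(1, 2), b@harmonic, b@field,
                           surf)$value, 0)
  expect_equal(tmTwoQuanta(vibState(c(1, 2)), b@harmonic, b@field,
                           surf)$value, 0)
  ## no derivatives at all: moment 0
  null <- scalarSurface(2)
  expect_equal(tmFundamental(1, b@harmonic, b@field, null)$value, 0)
})

test_that("pure electrical anharmonicity matches analytic oscillator integrals", {
  P2 <- array(0, c(2, 2, 1))
  P2[1, 1, 1] <- 0.004
  P2[1, 2, 1] <- P2[2, 1, 1] <- 0.003
  surf <- scalarSurface(2, P2 = P2)
  b <- mkBundle(c(900, 1500), props = list(electric_dipole = surf))
  ## overtone: (P_ii/2) <0|q^2|2> = P_ii * sqrt(2)/4
  m <- tmTwoQuanta(vibState(1, 2), b@harmonic, b@field, surf)
  expect_equal(m$value, 0.004 * sqrt(2) / 4)
  ## combination: P_ij <0|q|1>^2 = P_ij / 2
  mc <- tmTwoQuanta(vibState(c(1, 2)), b@harmonic, b@field, surf)
  expect_equal(mc$value, 0.003 / 2)
})

test_that("VPT2 moments agree with the dense variational oracle within 1%", {
  surf <- new("PropertySurface", name = "electric_dipole", nComponents = 1L,
              S = 1, s0 = 1, s1 = 1, s2 = 1, s3 = 1, P0 = 0.5,
              P1 = matrix(c(0.05, -0.03), 2, 1),
              P2 = array(c(0.004, 0.002, 0.002, -0.003), c(2, 2, 1)),
              P3 = list("1.1.2" = 0.0005), units = "au")
  b <- mkBundle(c(950, 1700),
                cubic = cubicDf(1, 1, 1, 6, 1, 1, 2, 5, 1, 2, 2, 4,
                                2, 2, 2, 3),
                quartic = quarticDf(1, 1, 1, 1, 4, 2, 2, 2, 2, 3,
                                    1, 1, 2, 2, 2),
                props = list(electric_dipole = surf))
  orc <- variationalOracle(b, nmax = 14)
  for (s in list(vibState(1), vibState(2), vibState(1, 2),
                 vibState(c(1, 2)))) {
    mv <- transitionMoment(s, b@harmonic, b@field, surf)$value
    mo <- oracleMoment(orc, s, surf)
    expect_lt(abs(mv - mo) / abs(mo), 0.01)
  }
})

test_that("momentum-type (S = -1) first-order moment uses the p element", {
  surf <- scalarSurface(2, P1 = c(0.02, 0), S = -1, name = "magnetic_dipole")
  b <- mkBundle(c(900, 1500), props = list(magnetic_dipole = surf))
  ## <0|p~|1> = -1/sqrt(2) in the real convention
  m <- tmFundamental(1, b@harmonic, b@field, surf)
  expect_equal(m$value, -0.02 / sqrt(2))
})

test_that("an untreated Fermi term diverges; deperturbation keeps it bounded", {
  surf <- scalarSurface(2, P1 = c(0.05, -0.03))
  momAt <- function(delta, resdb = NULL) {
    b <- mkBundle(c(800, 1600 + delta), cubic = cubicDf(1, 1, 2, 38),
                  props = list(electric_dipole = surf))
    rdb <- if (is.null(resdb)) NULL else
      buildResonanceDB(b@harmonic, b@field)
    abs(tmTwoQuanta(vibState(1, 2), b@harmonic, b@field, surf,
                    resdb = rdb)$value)
  }
  untreated <- vapply(c(8, 4, 2), momAt, numeric(1))
  expect_true(all(diff(untreated) > 0)) # grows without bound as the gap closes
  treated <- vapply(c(8, 4, 2, 0.5), momAt, numeric(1), resdb = TRUE)
  expect_lt(max(treated), untreated[1])
  ## and a near-singular untreated denominator is a hard error
  b <- mkBundle(c(800, 1600 + 1e-8), cubic = cubicDf(1, 1, 2, 38),
                props = list(electric_dipole = surf))
  expect_error(tmTwoQuanta(vibState(1, 2), b@harmonic, b@field, surf),
               "near-singular")
})

test_that("deperturbed contributions are ledgered per resonance", {
  b <- fermiDyadBundle()
  surf <- scalarSurface(2, P1 = c(0.05, -0.03))
  rdb <- buildResonanceDB(b@harmonic, b@field)
  m <- tmFundamental(2, b@harmonic, b@field, surf, resdb = rdb)
  expect_equal(m$level, "DVPT2")
  expect_true(gvpt2:::stateKeyV(c(2L, 0L)) %in% m$removed)
})

test_that("GVPT2 projection is an orthogonal mixing that conserves norms", {
  m <- matrix(c(1, 2, 0.5, -1), 2, 2,
              dimnames = list(c("1(1)", "1(2)"), NULL))
  ## identity eigenvectors: unchanged
  gvId <- new("GVPT2Result",
              blocks = list(list(states = rownames(m), matrix = diag(2),
                                 values = c(1, 2), vectors = diag(2),
                                 assignment = data.frame(level = 1:2,
                                                         energy = c(1, 2),
                                                         state = rownames(m),
                                                         overlap = 1,
                                                         tie = FALSE))),
              energies = c("1(1)" = 1, "1(2)" = 2),
              dvpt2 = c("1(1)" = 1, "1(2)" = 2))
  expect_equal(projectGvpt2(m, gvId), m)
  ## rotation by theta
  th <- 0.3
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  gvRot <- gvId
  gvRot@blocks[[1]]$vectors <- U
  got <- projectGvpt2(m, gvRot)
  expect_equal(unname(got), unname(t(U) %*% m))
  expect_equal(sum(got^2), sum(m^2), tolerance = 1e-12)
  ## random polyads conserve the summed squared norm to 1e-10 relative
  set.seed(14)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    st <- paste0("1(", seq_len(k), ")")
    mm <- matrix(stats::rnorm(k * 3), k, 3, dimnames = list(st, NULL))
    gv <- gvId
    gv@blocks[[1]] <- list(states = st, matrix = diag(k),
                           values = seq_len(k), vectors = Q,
                           assignment = data.frame(level = seq_len(k),
                                                   energy = seq_len(k),
                                                   state = st,
                                                   overlap = 1, tie = FALSE))
    got <- projectGvpt2(mm, gv)
    expect_lt(abs(sum(got^2) - sum(mm^2)) / sum(mm^2), 1e-10)
  }
})

test_that("full harmonic-limit pipeline reproduces double-harmonic sticks", {
  surf <- scalarSurface(2, P1 = c(0.05, -0.03))
  b <- mkBundle(c(900, 1500), props = list(electric_dipole = surf))
  rdb <- buildResonanceDB(b@harmonic, b@field)
  st <- stickTable(b, rdb, level = "GVPT2")
  expect_equal(st$table$energy[1:2], c(900, 1500))
  cst <- spectroConstants()
  expect_equal(st$table$D[1], 0.05^2 / 2 * cst$dipoleStrength)
  expect_equal(st$table$D[st$table$state == "2(1)"], 0)
})

test_that("pseudoeigenvectors reduce to L columns and reuse the cache", {
  b0 <- mkBundle(c(900, 1500))
  pe <- pseudoEigenvector(vibState(1), b0@harmonic, b0@field)
  expect_equal(pe$cartesian, as.numeric(b0@harmonic@L[, 1]))
  ## planted 1-1 mixing: the partner weight matches the mixing coefficient
  b <- mkBundle(c(1000, 1004.5),
                cubic = cubicDf(1, 1, 2, 12, 1, 2, 2, -9),
                quartic = quarticDf(1, 1, 1, 2, 24))
  cfg <- defaultResonanceConfig()
  cfg$dd11$energy$K <- Inf # analyze but do not deperturb
  cfg$dd11$intensity <- NULL
  rdb <- buildResonanceDB(b@harmonic, b@field, cfg)
  peC <- pseudoEigenvector(vibState(1), b@harmonic, b@field, rdb,
                           useCache = TRUE)
  peN <- pseudoEigenvector(vibState(1), b@harmonic, b@field, rdb,
                           useCache = FALSE)
  expect_equal(peC$coefficients, peN$coefficients, tolerance = 1e-12)
  idx <- ddIndex(vibState(1), vibState(2), b@harmonic, b@field, "R11COEF")
  expect_equal(abs(unname(peC$coefficients["2"])), idx$index,
               tolerance = 1e-10)
  ## 2-quanta state: first-order Fermi-type coefficients
  b2 <- mkBundle(c(800, 1640), cubic = cubicDf(1, 1, 2, 38))
  pe2 <- pseudoEigenvector(vibState(1, 2), b2@harmonic, b2@field)
  expect_equal(unname(pe2$coefficients["2"]),
               (38 / 4) / (1600 - 1640), tolerance = 1e-10)
})
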