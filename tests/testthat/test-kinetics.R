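# Closed-form pool and per-bond product kinetics, validated against limits,
# conservation laws and the numerical ODE oracle.

test_that("one-stage pools satisfy initial condition, asymptote and half-life", {
  kp <- kineticParams(k1 = 0.01, k2 = 0.003, km = 0, E = 10)  # k1E = 0.1
  p0 <- oneStagePools(0, kp, s01 = 1)
  expect_equal(p0$Sm1, 1)
  expect_equal(p0$Sd1, 0)
  pInf <- oneStagePools(1e6, kp, s01 = 1)
  expect_equal(pInf$Sm1, 0, tolerance = 1e-12)
  expect_equal(pInf$Sd1, 1, tolerance = 1e-12)
  pHalf <- oneStagePools(log(2) / 0.1, kp, s01 = 1)
  expect_equal(pHalf$Sm1, 0.5, tolerance = 1e-12)
  expect_error(oneStagePools(-1, kp), "nonnegative")
})

test_that("two-stage pools match initial condition, no-masking limit and the ODE oracle", {
  kp <- kineticParams(k1 = 0.1, k2 = 0.03, km = 0.075, E = 10)  # k1E=1, k2E=0.3
  p0 <- twoStagePools(0, kp, s02 = 1)
  expect_equal(unlist(p0[c("Sm2", "Sd2", "Sdd2")]), c(Sm2 = 1, Sd2 = 0, Sdd2 = 0))

  kp0 <- kineticParams(k1 = 0.1, k2 = 0.03, km = 0, E = 10)
  expect_equal(twoStagePools(1e5, kp0, s02 = 1)$Sdd2, 1, tolerance = 1e-10)

  # closed form vs numerical integration of the two-stage scheme
  tg <- seq(0, 5, by = 0.25)
  ode <- referenceODESolution(2, kp, times = tg)
  cf <- twoStagePools(tg, kp, s02 = 1)
  expect_lt(max(abs(cf$Sm2 - ode$Sm2)), 1e-8)
  expect_lt(max(abs(cf$Sd2 - ode$Sd2)), 1e-8)
  expect_lt(max(abs(cf$Sdd2 - ode$Sdd2)), 1e-8)

  # asymptote S02 k2E/(km + k2E)
  expect_equal(twoStagePools(1e4, kp, s02 = 1)$Sdd2, 0.3 / 0.375,
               tolerance = 1e-10)
  expect_error(twoStagePools(1, kineticParams(k1 = 0, k2 = 0.1, km = 0, E = 1)),
               "degenerate")
})

test_that("two-stage pools obey conservation with the secondary-masked pool", {
  kp <- kineticParams(k1 = 0.08, k2 = 0.02, km = 0.01, E = 7)
  tg <- seq(0, 60, by = 1)
  p <- twoStagePools(tg, kp, s02 = 1)
  smm <- (kp@km / (kp@k2 * kp@E)) * p$Sdd2
  expect_lt(max(abs(p$Sm2 + p$Sd2 + p$Sdd2 + smm - 1)), 1e-12)
})

test_that("one-stage bond products reach the masking-limited asymptote", {
  # kE = 0.16, km = 0.05 -> asymptote 2 * 0.16/0.21
  kp <- kineticParams(k1 = 0.016, k2 = 0.005, km = 0.05, E = 10)
  expect_equal(bondProductOneStage(1e5, n0 = 2, kappa = 1, kp),
               2 * 0.16 / 0.21, tolerance = 1e-9)
  kp0 <- kineticParams(k1 = 0.016, k2 = 0.005, km = 0, E = 10)
  expect_equal(bondProductOneStage(1e5, n0 = 2, kappa = 1, kp0), 2,
               tolerance = 1e-9)
  # bounded by the asymptote and monotone
  tg <- seq(0, 400, by = 2)
  v <- bondProductOneStage(tg, n0 = 2, kappa = 1, kp)
  expect_true(all(diff(v) > -1e-14))
  expect_true(all(v >= 0 & v <= 2 * 0.16 / 0.21 + 1e-12))
  expect_error(bondProductOneStage(1, n0 = 1, kappa = 0, kp), "kappa")
})

test_that("fast bonds are the large-kappa limit of one-stage bonds", {
  kp <- kineticParams(k1 = 0.05, k2 = 0.01, km = 0.002, E = 8)
  tg <- c(0.5, 2, 10, 50)
  fast <- bondProductFast(tg, n0 = 3, kp)
  slow <- bondProductOneStage(tg, n0 = 3, kappa = 1e6, kp)
  expect_lt(max(abs(fast - slow) / pmax(fast, 1e-12)), 1e-4)
  expect_equal(bondProductFast(0, 3, kp), 0)
  expect_equal(bondProductFast(1e6, 3, kp), 3)
})

test_that("two-stage bond products show a lag phase and match the ODE oracle", {
  kp <- kineticParams(k1 = 0.1, k2 = 0.03, km = 0.005, E = 10)  # k1E=1,k2E=0.3,kjE=0.35
  eps <- 1e-4
  early <- bondProductTwoStage(eps, n0 = 5, kappa = 0.35, kp)
  expect_equal(bondProductTwoStage(0, n0 = 5, kappa = 0.35, kp), 0)
  # zero initial slope: growth over [0, eps] is O(eps^3) for a 3-step chain
  expect_lt(early / eps, 1e-6)

  ode <- referenceODESolution(4, kp, times = c(0, 1, 5, 20), kappa = 0.35)
  cf <- bondProductTwoStage(c(0, 1, 5, 20), n0 = 1, kappa = 0.35, kp)
  expect_lt(max(abs(cf - ode$N)), 1e-8)

  kp0 <- kineticParams(k1 = 0.1, k2 = 0.03, km = 0, E = 10)
  expect_equal(bondProductTwoStage(1e5, n0 = 5, kappa = 0.35, kp0), 5,
               tolerance = 1e-9)
})

test_that("confluent rate constants use the analytic limit without blowing up", {
  # k1E == km + k2E exactly, and the near-confluent neighbourhood
  kpEq <- kineticParams(k1 = 0.1, k2 = 0.08, km = 0.2, E = 10)  # a1 = 1 = km+k2E
  tg <- seq(0, 8, by = 0.5)
  cf <- twoStagePools(tg, kpEq, s02 = 1)
  ode <- referenceODESolution(2, kpEq, times = tg)
  expect_lt(max(abs(cf$Sdd2 - ode$Sdd2)), 1e-8)
  expect_true(all(is.finite(cf$Sd2)))

  # triple confluence in the two-stage product chain: a1 = a2 = a3
  kpT <- kineticParams(k1 = 0.1, k2 = 0.05, km = 0.5, E = 10)  # a2 = 1
  cfT <- bondProductTwoStage(tg, n0 = 1, kappa = 1, kpT)       # a3 = 1
  odeT <- referenceODESolution(4, kpT, times = tg, kappa = 1)
  expect_lt(max(abs(cfT - odeT$N)), 1e-8)
})

test_that("degree of hydrolysis reproduces the dimensionless model asymptotes", {
  sub <- defaultSub()
  expect_equal(degreeOfHydrolysis(0, sub, dimensionlessParams(1, 0)), 0)
  # no masking: every specific bond is eventually cleaved
  expect_equal(degreeOfHydrolysis(1e6, sub, dimensionlessParams(0.7, 0)),
               15 / 161, tolerance = 1e-9)
  # kappa_m = 0.05, eps = 0.2: sum of class asymptotes
  asym <- (4 + 2 * 0.16 / 0.21 + 2 * 0.08 / 0.13 + 2 * 0.04 / 0.09 +
           5 * 0.06 / 0.11) / 161
  expect_equal(degreeOfHydrolysis(1e6, sub, dimensionlessParams(0.2, 0.05)),
               asym, tolerance = 1e-9)
  expect_error(degreeOfHydrolysis(1, substrateModel(0L, list()),
                                  dimensionlessParams(1)),
               "no peptide bonds")
})

test_that("d(t) is nondecreasing and its asymptote increases with enzyme when masking is active", {
  sub <- defaultSub()
  tg <- seq(0, 200, length.out = 400)
  for (eps in c(0.2, 2)) {
    d <- degreeOfHydrolysis(tg, sub, dimensionlessParams(eps, 0.05))
    expect_true(all(diff(d) > -1e-14))
  }
  dInf <- vapply(c(0.2, 0.4, 2, 5), function(eps)
    degreeOfHydrolysis(1e6, sub, dimensionlessParams(eps, 0.05)), numeric(1))
  expect_true(all(diff(dInf) > 0))
  # without masking the asymptote is enzyme-independent
  dInf0 <- vapply(c(0.2, 5), function(eps)
    degreeOfHydrolysis(1e6, sub, dimensionlessParams(eps, 0)), numeric(1))
  expect_equal(dInf0[1], dInf0[2], tolerance = 1e-12)
})

test_that("closed forms agree with the ODE oracle across random parameter draws", {
  set.seed(101)
  for (i in 1:25) {
    kp <- drawParams()
    a1 <- kp@k1 * kp@E
    tg <- seq(0, 10 / a1, length.out = 21)
    err <- numeric(0)

    o1 <- referenceODESolution(1, kp, times = tg)
    p1 <- oneStagePools(tg, kp, s01 = 1)
    err <- c(err, abs(p1$Sm1 - o1$Sm1), abs(p1$Sd1 - (o1$Sd1 + o1$Smm)))

    o2 <- referenceODESolution(2, kp, times = tg)
    p2 <- twoStagePools(tg, kp, s02 = 1)
    err <- c(err, abs(p2$Sm2 - o2$Sm2), abs(p2$Sd2 - o2$Sd2),
             abs(p2$Sdd2 - o2$Sdd2))

    kap <- exp(stats::runif(1, log(0.05), log(5)))
    o3 <- referenceODESolution(3, kp, times = tg, kappa = kap)
    err <- c(err, abs(bondProductOneStage(tg, 1, kap, kp) - o3$N))

    o4 <- referenceODESolution(4, kp, times = tg, kappa = kap)
    err <- c(err, abs(bondProductTwoStage(tg, 1, kap, kp) - o4$N))

    expect_lt(max(err), 1e-7)
  }
})

test_that("the ODE oracle itself conserves mass", {
  kp <- kineticParams(k1 = 0.05, k2 = 0.02, km = 0.01, E = 5)
  o4 <- referenceODESolution(4, kp, times = seq(0, 100, by = 5), kappa = 0.4)
  tot <- o4$Bm + o4$Bd + o4$Bmm + o4$Bdd + o4$N
  expect_lt(max(abs(tot - 1)), 1e-10)
})

test_that("dimensional and dimensionless parameterizations give the same curve", {
  kp <- kineticParams(k1 = 0.02, k2 = 0.006, km = 0.0015, E = 4.5, E0 = 10)
  dp <- toDimensionlessParams(kp)
  sub <- defaultSub()
  tMin <- c(1, 10, 60, 240)
  dDim <- degreeOfHydrolysis(tMin, sub, kp)
  dDml <- degreeOfHydrolysis(toDimensionlessTime(tMin, kp@k1, kp@E0), sub, dp)
  expect_equal(dDim, dDml, tolerance = 1e-12)

  # round trip is the identity
  back <- toKineticParams(dp, k1 = kp@k1, E0 = kp@E0)
  expect_equal(c(back@k1, back@k2, back@km, back@E, back@E0),
               c(kp@k1, kp@k2, kp@km, kp@E, kp@E0), tolerance = 1e-12)
})

test_that("tryptic bond inventory applies the Lys/Arg-not-before-Pro rule", {
  expect_equal(unname(trypticBondInventory("AKPMKR")), 1L)
  expect_equal(unname(trypticBondInventory("AAAA")), 0L)
  expect_equal(unname(trypticBondInventory("KRKR")), 3L)
  expect_equal(unname(trypticBondInventory(c(a = "KAKA", b = "RPRP"))),
               c(2L, 0L))
  expect_error(trypticBondInventory("AKZB"), "Z")
})

test_that("substrate and parameter validity rules reject inconsistent inputs", {
  expect_error(substrateModel(10L, list(bondClass(15, route = "fast"))),
               "totalBonds")
  expect_error(substrateModel(161L, list(bondClass(4, route = "fast")),
                              s01Fraction = 0.6, s02Fraction = 0.6),
               "sum to 1|equal 1")
  expect_error(dimensionlessParams(0), "epsilon")
  expect_error(kineticParams(k1 = -1, E = 1), "nonnegative")
  expect_error(bondClass(2, route = "one_stage"), "kappa")
})
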