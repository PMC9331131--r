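# Rate-versus-degree-of-hydrolysis analysis: rate curves, exponential slope
# b, drop-off point d*, and class decomposition.

test_that("the analytic initial rate comes from fast bonds only", {
  sub <- defaultSub()
  for (eps in c(0.2, 1, 5)) {
    dp <- dimensionlessParams(eps, 0.025)
    expect_equal(initialRate(sub, dp), 4 * eps / 161)
    cv <- hydrolysisRate(substrate = sub, params = dp)
    expect_equal(cv@provenance$r0, 4 * eps / 161)
    # rate decays to (nearly) zero along the default grid
    expect_lt(cv@r[length(cv@r)], cv@provenance$r0 / 500)
  }
})

test_that("analytic rates agree with finite differences of d on a dense grid", {
  sub <- defaultSub()
  dp <- dimensionlessParams(1.3, 0.03)
  tg <- seq(0, 30, length.out = 6001)
  d <- degreeOfHydrolysis(tg, sub, dp)
  cv <- hydrolysisRate(tg, sub, dp)
  h <- tg[2] - tg[1]
  mid <- 2:(length(tg) - 1)
  fd <- (d[mid + 1] - d[mid - 1]) / (2 * h)
  rel <- abs(cv@r[mid] - fd) / pmax(abs(fd), 1e-12)
  expect_lt(stats::quantile(rel, 0.99), 1e-5)
  expect_lt(stats::median(rel), 1e-6)
})

test_that("slope b is invariant under rescaling of the time axis", {
  sub <- defaultSub()
  dp <- dimensionlessParams(2, 0.05)
  cv1 <- hydrolysisRate(substrate = sub, params = dp)
  cv2 <- rateCurve(cv1@times / 3, cv1@d, cv1@r * 3,
                   provenance = list(r0 = cv1@provenance$r0 * 3))
  b1 <- slopeB(cv1); b2 <- slopeB(cv2)
  expect_equal(b1@b, b2@b, tolerance = 1e-9)
  expect_equal(b1@bAlt, b2@bAlt, tolerance = 1e-9)
  # with no secondary masking, b does not depend on enzyme concentration
  b0 <- vapply(c(0.2, 0.4, 2, 5), function(eps)
    slopeB(hydrolysisRate(substrate = sub,
                          params = dimensionlessParams(eps, 0)))@b, numeric(1))
  expect_lt(max(b0) - min(b0), 1e-4)  # residual spread is grid interpolation only
})

test_that("b increases and d* decreases as enzyme concentration falls under masking", {
  tab <- rateSummarySweep(kappaM = 0.05, epsilon = c(5, 2, 0.4, 0.2))
  expect_true(all(diff(tab$b) > 0))        # ordered eps 5 -> 0.2
  expect_true(all(diff(tab$d_star) < 0))
})

test_that("d* is the tenfold rate drop and is signalled when unreachable", {
  sub <- identicalBondSub()
  dp <- dimensionlessParams(1)
  cv <- hydrolysisRate(substrate = sub, params = dp)
  # analytic: r/r0 = 1 - d/dInf -> d* = 0.9 * 15/161
  expect_equal(dStar(cv), 0.9 * 15 / 161, tolerance = 1e-4)

  # truncated curve that never drops tenfold
  short <- hydrolysisRate(seq(0, 0.5, length.out = 200), substrate = sub,
                          params = dp)
  expect_warning(ds <- dStar(short), "never drops")
  expect_true(is.na(ds))
})

test_that("slopeB refuses an interval the curve cannot cover", {
  # heavy masking keeps d far below 0.05
  sub <- substrateModel(161L, list(bondClass(2, route = "fast"),
                                   bondClass(8, kappa = 0.3,
                                             route = "one_stage")))
  dp <- dimensionlessParams(0.5, 3)
  cv <- hydrolysisRate(substrate = sub, params = dp)
  expect_lt(max(cv@d), 0.05)
  expect_error(slopeB(cv), "max attainable")
})

test_that("class decomposition sums to the totals and shows the expected shapes", {
  sub <- defaultSub()
  dp <- dimensionlessParams(1.5, 0.02)
  tg <- seq(0, 25, length.out = 300)
  dec <- classDecomposition(tg, sub, dp)
  dTot <- attr(dec, "totalD"); rTot <- attr(dec, "totalR")
  sumD <- rowsum(dec$d, dec$t)[, 1]
  sumR <- rowsum(dec$r, dec$t)[, 1]
  expect_lt(max(abs(sumD - dTot)), 1e-12)
  expect_lt(max(abs(sumR - rTot)), 1e-12)
  expect_equal(dTot, degreeOfHydrolysis(tg, sub, dp), tolerance = 1e-12)

  # fast class is exactly 4(1 - exp(-eps tau))/161
  fast <- dec[dec$route == "fast", ]
  expect_equal(fast$d, 4 * (1 - exp(-1.5 * tg)) / 161, tolerance = 1e-12)

  # two-stage class lags: cubic-order start, far below the fast class share
  two <- dec[dec$route == "two_stage", ]
  expect_lt(two$d[2] / two$d[length(tg)], 1e-3)
  expect_lt(two$d[2] / two$d[length(tg)], 1e-2 * fast$d[2] / fast$d[length(tg)])
})

test_that("rate curves from sampled series reproduce model rates", {
  sub <- defaultSub()
  dp <- dimensionlessParams(2, 0.02)
  tg <- seq(0, 12, length.out = 60)
  d <- degreeOfHydrolysis(tg, sub, dp)
  cv <- rateCurveFromSeries(tg, d)
  truth <- hydrolysisRate(cv@times, sub, dp)
  expect_equal(cv@d, truth@d, tolerance = 1e-6)
  rel <- abs(cv@r - truth@r) / pmax(truth@r, 1e-9)
  expect_lt(stats::median(rel), 0.02)
})
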