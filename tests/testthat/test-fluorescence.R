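# Fluorescence-maximum observable, its long-time tail, and parabolic peak
# localization of emission spectra.

test_that("model lambda_max starts at lambda1 and ends at the mixture asymptote", {
  sub <- defaultSub()
  dp <- dimensionlessParams(1.5, 0)
  expect_equal(lambdaMaxModel(0, sub, dp), sub@lambda1)
  # no secondary masking: asymptote is s01 lambda2 + s02 lambda3
  lev <- lambdaLevels(sub); fr <- poolFractions(sub)
  expect_equal(lambdaMaxModel(1e6, sub, dp),
               unname(fr["s01"] * lev["lambda2"] + fr["s02"] * lev["lambda3"]),
               tolerance = 1e-9)
})

test_that("the closed tail approximates the full observable at long times", {
  sub <- defaultSub()
  for (par in list(dimensionlessParams(2, 0.01),
                   kineticParams(k1 = 0.02, k2 = 0.006, km = 0.001, E = 15))) {
    a1 <- if (is(par, "KineticParams")) par@k1 * par@E else par@epsilon
    tg <- seq(10 / a1, 40 / a1, length.out = 50)
    expect_lt(max(abs(lambdaMaxModel(tg, sub, par) -
                      lambdaMaxTail(tg, sub, par))), 0.01)
  }
})

test_that("tail rate equals km + k2E independently of the fluorescence levels", {
  kp <- kineticParams(k1 = 0.02, k2 = 0.006, km = 0.0015, E = 4.5)
  tp1 <- tailParameters(defaultSub(), kp)
  expect_equal(tp1$rate, kp@km + kp@k2 * kp@E)
  sub2 <- betaLgSubstrate(lambda2 = 344)
  expect_equal(tailParameters(sub2, kp)$rate, tp1$rate)

  # kappa_m = 0 collapses the asymptote to the unmasked mixture
  kp0 <- kineticParams(k1 = 0.02, k2 = 0.006, km = 0, E = 4.5)
  tp0 <- tailParameters(defaultSub(), kp0)
  fr <- poolFractions(defaultSub()); lev <- lambdaLevels(defaultSub())
  expect_equal(tp0$lambdaStar,
               unname(fr["s01"] * lev["lambda2"] + fr["s02"] * lev["lambda3"]))
})

test_that("the tail asymptote increases strictly with enzyme concentration under masking", {
  sub <- defaultSub()
  ls <- vapply(c(0.2, 0.4, 2, 5), function(eps)
    tailParameters(sub, dimensionlessParams(eps, 0.05))$lambdaStar, numeric(1))
  expect_true(all(diff(ls) > 0))
  ls0 <- vapply(c(0.2, 5), function(eps)
    tailParameters(sub, dimensionlessParams(eps, 0))$lambdaStar, numeric(1))
  expect_equal(ls0[1], ls0[2])
})

test_that("lambda_max is a bounded, redshifting observable in the masking-free model", {
  sub <- defaultSub()
  tg <- seq(0, 500, length.out = 800)
  for (eps in c(0.3, 2)) {
    lm0 <- lambdaMaxModel(tg, sub, dimensionlessParams(eps, 0))
    expect_true(all(lm0 >= sub@lambda1 - 1e-9))
    expect_true(all(lm0 <= max(sub@lambda2, sub@lambda3) + 1e-9))
  }
  # one-stage-only substrate: monotone redshift at any masking level
  s1 <- oneStageOnlySub()
  lm1 <- lambdaMaxModel(tg, s1, dimensionlessParams(1, 0.05))
  expect_true(all(diff(lm1) > -1e-12))
})

test_that("parabolic peak recovers symmetric and exact-parabola spectra", {
  # symmetric 5-point spectrum around 352
  sp <- emissionSpectrum(c(348, 350, 352, 354, 356),
                         c(0.7, 1.0, 1.2, 1.0, 0.7))
  expect_warning(pk <- parabolicPeak(sp), "window")
  expect_equal(pk, 352, tolerance = 1e-9)

  wl <- seq(340, 360, by = 1)
  sp2 <- emissionSpectrum(wl, -(wl - 351)^2 + 5)
  expect_warning(pk2 <- parabolicPeak(sp2), "window")
  expect_equal(pk2, 351, tolerance = 1e-9)
})

test_that("parabolic peak is invariant under affine intensity rescaling", {
  wl <- seq(310, 400, by = 0.5)
  int <- exp(-(wl - 353.2)^2 / 900)
  p1 <- parabolicPeak(emissionSpectrum(wl, int))
  p2 <- parabolicPeak(emissionSpectrum(wl, 7.3 * int + 2.1))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("parabolic peak rejects non-concave fits and tiny windows", {
  wl <- seq(340, 360, by = 1)
  expect_error(suppressWarnings(parabolicPeak(emissionSpectrum(wl, (wl - 350)^2))),
               "concave")
  sp <- emissionSpectrum(c(349, 350, 351), c(0.9, 1, 0.9))
  expect_error(suppressWarnings(parabolicPeak(sp)), "5 points")
})

test_that("parabolic peak localizes a noisy Gaussian band within 0.3 nm", {
  wl <- seq(300, 420, by = 0.5)
  band <- exp(-4 * log(2) * (wl - 353)^2 / 60^2)
  set.seed(7)
  errs <- replicate(100, {
    sp <- emissionSpectrum(wl, band + rnorm(length(wl), 0, 0.01))
    parabolicPeak(sp) - 353
  })
  expect_lt(mean(abs(errs)), 0.15)
  expect_lt(unname(stats::quantile(abs(errs), 0.95)), 0.3)
})
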