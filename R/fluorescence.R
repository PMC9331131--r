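## Tryptophan fluorescence observable: the position of the emission maximum
## is a concentration-weighted mixture of three levels (masked, partially
## demasked, fully demasked), so the redshift traces the demasking state of
## the substrate.

#' Model fluorescence maximum
#'
#' The position of the tryptophan emission maximum as a concentration-
#' weighted mean of the three fluorescence levels over the substrate pools:
#' masked pools at lambda1, partially demasked pools at lambda2, and the
#' fully demasked pool at lambda3. At t = 0 the value is lambda1; with no
#' secondary masking it tends to (s01 lambda2 + s02 lambda3).
#'
#' @param t time (min, or dimensionless tau with
#'   \linkS4class{DimensionlessParams}).
#' @param substrate a \linkS4class{SubstrateModel} (pool fractions and
#'   fluorescence levels are taken from it).
#' @param params a \linkS4class{KineticParams} or
#'   \linkS4class{DimensionlessParams}.
#' @return numeric vector of lambda_max values (nm).
#' @examples
#' lambdaMaxModel(c(0, 10, 100), betaLgSubstrate(),
#'                dimensionlessParams(epsilon = 1.5, kappaM = 0.01))
#' @export
lambdaMaxModel <- function(t, substrate, params) {
  p1 <- oneStagePools(t, params, s01 = substrate@s01Fraction)
  p2 <- twoStagePools(t, params, s02 = substrate@s02Fraction)
  (p1$Sm1 * substrate@lambda1 + p1$Sd1 * substrate@lambda2 +
   p2$Sm2 * substrate@lambda1 + p2$Sd2 * substrate@lambda2 +
   p2$Sdd2 * substrate@lambda3)
}

#' Long-time tail parameters of the fluorescence maximum
#'
#' The single-exponential approximation valid for t >> 1/(k1 E): lambda_max
#' approaches the asymptote lambda* = s01 lambda2 + s02 lambda3 k2E/(km+k2E)
#' with amplitude a and rate k = km + k2E. The rate is independent of the
#' fluorescence levels, which is what makes the tail fit an estimator of
#' km + k2 E; regressing k on E then separates km (intercept) from k2
#' (slope).
#'
#' @inheritParams lambdaMaxModel
#' @return For \code{tailParameters}, a list with \code{lambdaStar},
#'   \code{amplitude} and \code{rate}; for \code{lambdaMaxTail}, the tail
#'   values at \code{t}.
#' @examples
#' tailParameters(betaLgSubstrate(), kineticParams(k1 = 0.02, k2 = 0.006,
#'                km = 0.0015, E = 15))
#' @export
tailParameters <- function(substrate, params) {
  rs <- .rates(params)
  beta <- rs$km + rs$k2E
  s01 <- substrate@s01Fraction; s02 <- substrate@s02Fraction
  l2 <- substrate@lambda2; l3 <- substrate@lambda3
  if (beta == 0) {
    if (s02 > 0 && rs$k2E == 0)
      stop("tail undefined: the two-stage pool never completes demasking (km = k2E = 0)")
    return(list(lambdaStar = s01 * l2 + s02 * l3, amplitude = 0, rate = 0))
  }
  if (.close(rs$a1, beta))
    stop("tail form undefined when k1 E equals km + k2 E (confluent exponentials)")
  lambdaStar <- s01 * l2 + s02 * l3 * rs$k2E / beta
  amplitude <- s02 * rs$a1 / (rs$a1 - beta) * (l3 * rs$k2E / beta - l2)
  list(lambdaStar = lambdaStar, amplitude = amplitude, rate = beta)
}

#' @rdname tailParameters
#' @export
lambdaMaxTail <- function(t, substrate, params) {
  .checkTime(t)
  tp <- tailParameters(substrate, params)
  tp$lambdaStar - tp$amplitude * exp(-tp$rate * t)
}

#' Parabolic localization of an emission peak
#'
#' Estimates the wavelength of the emission maximum by least-squares fitting
#' a parabola I(lambda) = a lambda^2 + b lambda + c over a window centered on
#' the discrete intensity maximum and returning the vertex -b/(2a). The fit
#' requires a concave parabola (a < 0). The estimate is invariant under
#' affine rescaling of the intensities.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param window window width in nm (default 30) centered on the discrete
#'   argmax; a window truncated by the data range is used with a warning as
#'   long as at least 5 points remain.
#' @return Peak wavelength in nm.
#' @examples
#' wl <- seq(320, 380, by = 1)
#' parabolicPeak(emissionSpectrum(wl, -(wl - 351)^2 + 5))
#' @export
parabolicPeak <- function(spectrum, window = 30) {
  wl <- spectrum@wavelengths
  int <- spectrum@intensities
  ctr <- wl[which.max(int)]
  lo <- ctr - window / 2; hi <- ctr + window / 2
  if (lo < min(wl) || hi > max(wl))
    warning("fitting window extends beyond the spectrum; proceeding with the truncated window")
  sel <- wl >= lo & wl <= hi
  if (sum(sel) < 5L)
    stop("fewer than 5 points in the fitting window")
  x <- wl[sel] - ctr  # center for conditioning
  y <- int[sel]
  fit <- stats::lm(y ~ x + I(x^2))
  a <- stats::coef(fit)[["I(x^2)"]]
  b <- stats::coef(fit)[["x"]]
  if (!is.finite(a) || a >= 0)
    stop("peak detection failed: fitted parabola is not concave")
  ctr - b / (2 * a)
}
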