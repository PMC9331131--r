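## ln(rate)-versus-degree-of-hydrolysis analysis: the empirical exponential
## proteolysis model r = a exp(-b d) linearizes to ln r = ln a - b d. The
## slope b over a fixed early interval of d and the drop-off point d* (where
## the rate has fallen tenfold below its initial value) summarize how fast
## proteolysis self-decelerates.

#' Construct a rate curve
#'
#' @param times time grid (min or dimensionless).
#' @param d degree of hydrolysis at each time.
#' @param r hydrolysis rate at each time.
#' @param provenance metadata list; model-derived curves should carry the
#'   analytic initial rate as \code{r0}.
#' @return A \linkS4class{RateCurve}. Points where d fails to increase
#'   (numerically flat asymptote) are dropped.
#' @export
rateCurve <- function(times, d, r, provenance = list()) {
  keep <- c(TRUE, diff(d) > 0)
  new("RateCurve", times = times[keep], d = d[keep], r = r[keep],
      provenance = provenance)
}

#' Model hydrolysis-rate trajectory
#'
#' Computes the parametric curve (d(t), r(t)) for a substrate and parameter
#' set, with the rate obtained by term-wise analytic differentiation of the
#' closed-form solutions (sums of exponentials). The analytic initial rate
#' (the t -> 0+ limit, to which only fast bonds contribute) is stored in the
#' provenance.
#'
#' @param times time grid; if NULL, a dense default grid covering the drop-off
#'   region is chosen (see \code{\link{defaultTimeGrid}}).
#' @param substrate a \linkS4class{SubstrateModel}.
#' @param params a \linkS4class{KineticParams} or
#'   \linkS4class{DimensionlessParams}.
#' @return A \linkS4class{RateCurve}.
#' @examples
#' hydrolysisRate(substrate = betaLgSubstrate(),
#'                params = dimensionlessParams(epsilon = 2, kappaM = 0.05))
#' @export
hydrolysisRate <- function(times = NULL, substrate, params) {
  if (is.null(times)) times <- defaultTimeGrid(substrate, params)
  .checkTime(times)
  ck <- .classKinetics(times, substrate, params)
  B0 <- substrate@totalBonds
  rateCurve(times, rowSums(ck$d) / B0, rowSums(ck$r) / B0,
            provenance = list(r0 = initialRate(substrate, params),
                              params = params, substrate = substrate@name))
}

#' Default dense time grid for rate analysis
#'
#' Uniform grid from 0 to the time at which the hydrolysis rate has decayed
#' to 1/1000 of its analytic initial value, which comfortably covers the
#' tenfold-drop point d*.
#'
#' @inheritParams hydrolysisRate
#' @param n number of grid points.
#' @return numeric time grid.
#' @export
defaultTimeGrid <- function(substrate, params, n = 8001L) {
  r0 <- initialRate(substrate, params)
  if (r0 <= 0) stop("initial rate is zero: no fast bonds in the substrate")
  tmax <- 1
  ck <- function(t) sum(.classKinetics(t, substrate, params)$r) / substrate@totalBonds
  while (ck(tmax) > r0 / 1000 && tmax < 1e7) tmax <- tmax * 1.5
  seq(0, tmax, length.out = n)
}

#' Slope of ln(rate) versus degree of hydrolysis
#'
#' Fits ln r = -b d + const by ordinary least squares at \code{nPoints}
#' points uniformly spaced in d over \code{interval}, and returns the negated
#' slope. Times at the sample points are obtained by interpolating the
#' monotone parametric curve. Two conventions for the rate at the sample
#' points are computed: \code{"difference"} (default) takes central finite
#' differences of (t, d) at the sample points, with the analytic initial
#' rate at the left endpoint and the final point dropped, mirroring how
#' rates are extracted from sampled hydrolysis data; \code{"analytic"}
#' interpolates the curve's stored (analytic) ln r. Both estimates are kept:
#' the one selected by \code{rateMethod} in \code{b}, the other in
#' \code{bAlt} as a sampling-sensitivity diagnostic. The slope is invariant
#' under rescaling of the time axis, hence for kappaM = 0 it does not depend
#' on the enzyme concentration.
#'
#' @param curve a \linkS4class{RateCurve} covering the interval.
#' @param interval fit interval in d, default [0, 0.05].
#' @param nPoints number of uniform-d sample points (default 51).
#' @param rateMethod \code{"difference"} or \code{"analytic"}.
#' @return A \linkS4class{SlopeResult}.
#' @examples
#' cv <- hydrolysisRate(substrate = betaLgSubstrate(),
#'                      params = dimensionlessParams(epsilon = 2, kappaM = 0))
#' slopeB(cv)
#' @export
slopeB <- function(curve, interval = c(0, 0.05), nPoints = 51L,
                   rateMethod = c("difference", "analytic")) {
  rateMethod <- match.arg(rateMethod)
  d <- curve@d; r <- curve@r; tt <- curve@times
  if (max(d) < interval[2])
    stop(sprintf("curve does not reach d = %g (max attainable d = %.5g)",
                 interval[2], max(d)))
  if (min(d) > interval[1] + 1e-9 * max(1, abs(interval[2])))
    stop(sprintf("curve starts above d = %g (min d = %.5g)",
                 interval[1], min(d)))
  dd <- seq(interval[1], interval[2], length.out = nPoints)
  dd[1] <- max(dd[1], min(d))  # absorb rounding residue at t = 0
  ts <- stats::approx(d, tt, xout = dd)$y

  ## analytic convention: interpolate ln r along the curve
  lnrA <- stats::approx(d, log(r), xout = dd)$y
  fitA <- stats::lm(lnrA ~ dd)
  bA <- -unname(stats::coef(fitA)[2])

  ## difference convention: central differences of (t, d) at the sample
  ## points; analytic r0 at the left end, last point dropped
  np <- nPoints
  rD <- rep(NA_real_, np)
  rD[2:(np - 1)] <- (dd[3:np] - dd[1:(np - 2)]) / (ts[3:np] - ts[1:(np - 2)])
  r0 <- curve@provenance$r0
  rD[1] <- if (!is.null(r0)) r0 else (dd[2] - dd[1]) / (ts[2] - ts[1])
  ok <- is.finite(rD) & rD > 0
  fitD <- stats::lm(log(rD[ok]) ~ dd[ok])
  bD <- -unname(stats::coef(fitD)[2])

  if (rateMethod == "difference") {
    fit <- fitD; b <- bD; alt <- bA
  } else {
    fit <- fitA; b <- bA; alt <- bD
  }
  new("SlopeResult", b = b, bSE = summary(fit)$coefficients[2, 2],
      intercept = unname(stats::coef(fit)[1]),
      interval = as.numeric(interval), nPoints = as.integer(nPoints),
      rateMethod = rateMethod, bAlt = alt)
}

#' Drop-off point of the hydrolysis rate
#'
#' The smallest degree of hydrolysis at which the rate has fallen tenfold
#' below its initial value, i.e. where ln r first reaches ln r0 - ln 10.
#' For model curves r0 is the analytic limit stored in the curve provenance;
#' for experimental curves it defaults to the first-point rate. Located by
#' bracketing and linear interpolation in (d, ln r).
#'
#' @param curve a \linkS4class{RateCurve}.
#' @param r0 initial rate; default from the curve provenance, else the first
#'   rate value.
#' @return d* as a single numeric, or NA (with a warning) when the criterion
#'   is never met within the curve.
#' @examples
#' cv <- hydrolysisRate(substrate = betaLgSubstrate(),
#'                      params = dimensionlessParams(epsilon = 5, kappaM = 0.05))
#' dStar(cv)
#' @export
dStar <- function(curve, r0 = NULL) {
  if (is.null(r0)) r0 <- curve@provenance$r0
  if (is.null(r0)) r0 <- curve@r[1]
  lnr <- log(curve@r)
  thr <- log(r0) - log(10)
  idx <- which(lnr <= thr)[1]
  if (is.na(idx)) {
    warning(sprintf("rate never drops tenfold below r0 within the curve (max decline %.3f log units)",
                    log(r0) - min(lnr, na.rm = TRUE)))
    return(NA_real_)
  }
  if (idx == 1L) return(curve@d[1])
  d0 <- curve@d[idx - 1]; d1 <- curve@d[idx]
  l0 <- lnr[idx - 1]; l1 <- lnr[idx]
  d0 + (thr - l0) * (d1 - d0) / (l1 - l0)
}

#' Slope/drop-off sweep over masking and enzyme levels
#'
#' Runs the dimensionless model over a grid of secondary-masking constants
#' and enzyme concentrations and tabulates the exponential-model slope b
#' (with its standard error) and the drop-off point d* for each combination.
#'
#' @param kappaM vector of dimensionless secondary masking rate constants.
#' @param epsilon vector of dimensionless enzyme concentrations.
#' @param substrate a \linkS4class{SubstrateModel}.
#' @param kappa2 ratio k2/k1 for the two-stage route.
#' @param interval fit interval in d for the slope.
#' @param nPoints number of uniform-d sample points for the slope fit.
#' @param rateMethod rate convention passed to \code{\link{slopeB}}.
#' @return data.frame with columns \code{kappa_m}, \code{epsilon}, \code{b},
#'   \code{b_se}, \code{d_star}.
#' @examples
#' rateSummarySweep(kappaM = c(0, 0.05), epsilon = c(2, 5))
#' @export
rateSummarySweep <- function(kappaM = c(0.05, 0.025, 0),
                             epsilon = c(5, 2, 0.4, 0.2),
                             substrate = betaLgSubstrate(), kappa2 = 0.3,
                             interval = c(0, 0.05), nPoints = 51L,
                             rateMethod = "difference") {
  grid <- expand.grid(epsilon = epsilon, kappa_m = kappaM)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    dp <- dimensionlessParams(epsilon = grid$epsilon[i],
                              kappaM = grid$kappa_m[i], kappa2 = kappa2)
    cv <- hydrolysisRate(substrate = substrate, params = dp)
    sb <- slopeB(cv, interval = interval, nPoints = nPoints,
                 rateMethod = rateMethod)
    data.frame(kappa_m = grid$kappa_m[i], epsilon = grid$epsilon[i],
               b = sb@b, b_se = sb@bSE, d_star = dStar(cv))
  }))
  out[order(-out$kappa_m, -out$epsilon), , drop = FALSE]
}

#' Rate curve from a sampled degree-of-hydrolysis series
#'
#' Builds a \linkS4class{RateCurve} from experimental (t, d) samples: d(t)
#' is interpolated by a monotone piecewise-cubic spline (optionally) and
#' differentiated to give the rate; the initial rate is the first-point
#' derivative.
#'
#' @param t sample times.
#' @param d degree-of-hydrolysis values.
#' @param smooth logical; interpolate with a monotone Hermite spline before
#'   differentiating (default TRUE). With FALSE, central finite differences
#'   of the raw samples are used.
#' @param n number of points on the refined grid when smoothing.
#' @return A \linkS4class{RateCurve} with provenance \code{r0} set to the
#'   first-point rate.
#' @export
rateCurveFromSeries <- function(t, d, smooth = TRUE, n = 512L) {
  ord <- order(t)
  t <- t[ord]; d <- d[ord]
  if (smooth) {
    f <- stats::splinefun(t, d, method = "hyman")
    tg <- seq(min(t), max(t), length.out = n)
    dg <- f(tg)
    rg <- f(tg, deriv = 1)
    rateCurve(tg, dg, rg, provenance = list(r0 = f(min(t), deriv = 1),
                                            source = "series"))
  } else {
    nn <- length(t)
    r <- rep(NA_real_, nn)
    r[2:(nn - 1)] <- (d[3:nn] - d[1:(nn - 2)]) / (t[3:nn] - t[1:(nn - 2)])
    r[1] <- (d[2] - d[1]) / (t[2] - t[1])
    r[nn] <- (d[nn] - d[nn - 1]) / (t[nn] - t[nn - 1])
    rateCurve(t, d, r, provenance = list(r0 = r[1], source = "series"))
  }
}
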