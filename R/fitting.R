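## Parameter estimation from observables: nonlinear tail fits of
## lambda_max(t), the linear enzyme-titration regression k = km + k2 E that
## separates the non-enzymatic masking rate from the enzymatic demasking
## rate, and degree of hydrolysis from amino-nitrogen (OPA) readings.

#' Fit the exponential tail of a fluorescence-maximum series
#'
#' Nonlinear least squares of lambda_max(t) = lambda* - a exp(-k t) on the
#' points with t >= \code{tMin}. The tail model holds at long times
#' (t >> 1/(k1 E)), so a cutoff is applied; by default it is one third of
#' the time at which the series first comes within 1 nm of its running
#' maximum. Initialization: lambda*_0 is the maximum observed value, a_0 the
#' gap from the first used point, and k_0 the log-linear regression rate of
#' (lambda*_0 + 0.5 - lambda_max). Standard errors come from the linearized
#' covariance at the optimum.
#'
#' A constant series is degenerate: lambda* is the constant, the amplitude
#' is 0 and the rate is unidentifiable (flagged, rate NA).
#'
#' @param t times (min).
#' @param lambdaMax observed fluorescence maxima (nm).
#' @param tMin cutoff time; points earlier than this are excluded.
#' @return A \linkS4class{TailFit}.
#' @examples
#' tt <- seq(2, 120, by = 4)
#' y <- 353.7 - 10 * exp(-0.065 * tt)
#' fitTail(tt, y)
#' @export
fitTail <- function(t, lambdaMax, tMin = NULL) {
  stopifnot(length(t) == length(lambdaMax))
  ord <- order(t)
  t <- t[ord]; y <- lambdaMax[ord]
  if (is.null(tMin)) {
    near <- which(y >= max(y) - 1)[1]
    tMin <- t[near] / 3
  }
  use <- t >= tMin
  if (sum(use) < 4L)
    stop(sprintf("need at least 4 points with t >= %.4g for the tail fit (%d available)",
                 tMin, sum(use)))
  tt <- t[use]; yy <- y[use]
  if (diff(range(yy)) < 1e-12) {
    return(new("TailFit", lambdaStar = yy[1], amplitude = 0, rate = NA_real_,
               se = c(lambdaStar = 0, amplitude = 0, rate = NA_real_),
               rSquared = NA_real_, n = length(yy), tMin = tMin,
               degenerate = TRUE))
  }
  ls0 <- max(yy)
  a0 <- max(ls0 - yy[1], 1e-3)
  gap <- ls0 + 0.5 - yy
  k0 <- -unname(stats::coef(stats::lm(log(gap) ~ tt))[2])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / stats::median(tt)
  fit <- try(minpack.lm::nlsLM(
    yy ~ ls - a * exp(-k * tt),
    start = list(ls = ls0, a = a0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    resid0 <- sqrt(sum((yy - (ls0 - a0 * exp(-k0 * tt)))^2))
    stop(sprintf("tail fit did not converge (start lambda* = %.2f, a = %.2f, k = %.4g; residual norm %.3g): %s",
                 ls0, a0, k0, resid0, as.character(fit)))
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((yy - mean(yy))^2)
  new("TailFit", lambdaStar = unname(cf["ls"]), amplitude = unname(cf["a"]),
      rate = unname(cf["k"]),
      se = c(lambdaStar = unname(se["ls"]), amplitude = unname(se["a"]),
             rate = unname(se["k"])),
      rSquared = 1 - rss / tss, n = length(yy), tMin = tMin,
      degenerate = FALSE)
}

#' Separate masking and demasking rates from an enzyme titration
#'
#' Ordinary least squares of the tail rates k against enzyme concentration:
#' k = km + k2 E. The intercept estimates the non-enzymatic secondary
#' masking rate constant km, the slope the second-stage demasking rate
#' constant k2, and their ratio km/k2 (mg/L) expresses how much enzyme is
#' needed for demasking to outpace masking. Scaling all E by a constant c
#' scales k2 by 1/c and leaves km unchanged.
#'
#' @param E enzyme concentrations (mg/L), or a data.frame with columns
#'   \code{E} and \code{k}.
#' @param k fitted tail rates (min^-1), one per enzyme concentration.
#' @return list with \code{km}, \code{k2}, \code{ratio} (= km/k2),
#'   standard errors \code{kmSE}, \code{k2SE}, \code{ratioSE} (delta
#'   method), and the underlying \code{fit}. A non-positive k2 triggers a
#'   warning (model inconsistency) but values are still returned.
#' @examples
#' estimateKmK2(E = c(15, 4.5, 0.9), k = c(0.065, 0.019, 0.006))
#' @export
estimateKmK2 <- function(E, k = NULL) {
  if (is.data.frame(E)) { k <- E$k; E <- E$E }
  if (length(unique(E)) < 2L)
    stop("need at least 2 distinct enzyme concentrations")
  fit <- stats::lm(k ~ E)
  cf <- stats::coef(fit)
  km <- unname(cf[1]); k2 <- unname(cf[2])
  sm <- suppressWarnings(summary(fit))$coefficients  # a flat titration is "perfect"
  kmSE <- if (nrow(sm) == 2 && stats::df.residual(fit) > 0) sm[1, 2] else NA_real_
  k2SE <- if (nrow(sm) == 2 && stats::df.residual(fit) > 0) sm[2, 2] else NA_real_
  if (k2 <= 0)
    warning("fitted k2 <= 0: tail rates do not increase with enzyme concentration")
  ratio <- km / k2
  ratioSE <- if (is.finite(kmSE) && is.finite(k2SE) && k2 != 0) {
    vc <- suppressWarnings(stats::vcov(fit))
    abs(ratio) * sqrt(kmSE^2 / km^2 + k2SE^2 / k2^2 -
                      2 * vc[1, 2] / (km * k2))
  } else NA_real_
  list(km = km, k2 = k2, ratio = ratio, kmSE = kmSE, k2SE = k2SE,
       ratioSE = ratioSE, fit = fit)
}

#' Degree of hydrolysis from amino-nitrogen readings
#'
#' Converts an amino-nitrogen (or absorbance proxy) time series from the
#' o-phthalaldehyde assay to degree of hydrolysis: d = (N(t) - N0) / deltaN,
#' where deltaN is the amino nitrogen released by complete hydrolysis.
#' Values outside [0, 1] beyond \code{tol} are reported via a warning and an
#' \code{outOfRange} attribute but are not clamped.
#'
#' @param t times (min).
#' @param N amino-nitrogen readings (consistent units).
#' @param N0 reading at time zero (default: first value).
#' @param deltaN reading increment for complete hydrolysis; must be > 0.
#' @param tol noise tolerance for the out-of-range report.
#' @return data.frame with columns \code{t} and \code{d}.
#' @examples
#' dhFromOpa(t = c(0, 5, 10), N = c(0.10, 0.25, 0.40), deltaN = 2)
#' @export
dhFromOpa <- function(t, N, N0 = N[1], deltaN, tol = 0.02) {
  if (!is.finite(deltaN) || deltaN <= 0)
    stop("deltaN must be > 0")
  d <- (N - N0) / deltaN
  oor <- which(d < -tol | d > 1 + tol)
  out <- data.frame(t = t, d = d)
  if (length(oor)) {
    warning(sprintf("%d degree-of-hydrolysis value(s) outside [0, 1] beyond tolerance; reported unclamped",
                    length(oor)))
    attr(out, "outOfRange") <- oor
  }
  out
}
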