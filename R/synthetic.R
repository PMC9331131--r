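## Seeded generators for the observables the analysis consumes: emission
## spectra with a drifting peak, fluorescence-maximum series and
## degree-of-hydrolysis series. Generators are pure functions of
## (configuration, seed) and embed their ground truth so that recovery can
## be scored automatically.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.groundTruth <- function(model, substrate, params, noise, extra = list()) {
  c(list(model = model, substrate = substrate@name,
         params = params, noise = noise), extra)
}

#' Generate a fluorescence-maximum time series
#'
#' Forward-simulates lambda_max(t) from the pool model and adds Gaussian
#' noise of sd \code{sigmaLambda}. The true model values and full
#' configuration are embedded as the \code{groundTruth} attribute.
#'
#' @param substrate a \linkS4class{SubstrateModel}.
#' @param params a \linkS4class{KineticParams} or
#'   \linkS4class{DimensionlessParams}.
#' @param times sampling times.
#' @param noise a \linkS4class{NoiseSpec}.
#' @return data.frame with columns \code{t}, \code{lambda_max}; attribute
#'   \code{groundTruth}.
#' @examples
#' generateLambdaSeries(betaLgSubstrate(),
#'                      kineticParams(k1 = 0.02, k2 = 0.006, km = 0.0015, E = 15),
#'                      times = seq(0, 120, by = 4), noise = noiseSpec(seed = 7))
#' @export
generateLambdaSeries <- function(substrate, params, times, noise = noiseSpec()) {
  mu <- lambdaMaxModel(times, substrate, params)
  y <- .withSeed(noise@seed,
                 mu + stats::rnorm(length(times), 0, noise@sigmaLambda))
  out <- data.frame(t = times, lambda_max = y)
  attr(out, "groundTruth") <- .groundTruth("lambdaMaxModel", substrate,
                                           params, noise,
                                           list(truth = mu))
  out
}

#' Generate a series of emission spectra
#'
#' Produces one spectrum per time point: a Gaussian emission band (default
#' FWHM 60 nm) whose true peak position equals the model lambda_max at that
#' time, with unit peak height, plus additive Gaussian intensity noise.
#' Applying \code{\link{parabolicPeak}} to the noiseless output recovers the
#' model peak to well under 0.05 nm.
#'
#' @inheritParams generateLambdaSeries
#' @param wavelengths wavelength grid (nm), default 300-420 at 0.5 nm.
#' @param fwhm full width at half maximum of the band (nm).
#' @param bandShape optional function(wavelength, center) giving a unimodal
#'   band; default Gaussian with the given FWHM.
#' @return list of \linkS4class{Spectrum}; attribute \code{groundTruth}
#'   carries the true peak positions.
#' @export
generateSpectraSeries <- function(substrate, params, times,
                                  noise = noiseSpec(),
                                  wavelengths = seq(300, 420, by = 0.5),
                                  fwhm = 60, bandShape = NULL) {
  if (is.null(bandShape))
    bandShape <- function(wl, center) exp(-4 * log(2) * (wl - center)^2 / fwhm^2)
  mu <- lambdaMaxModel(times, substrate, params)
  spectra <- .withSeed(noise@seed, lapply(seq_along(times), function(i) {
    int <- bandShape(wavelengths, mu[i])
    if (noise@sigmaIntensity > 0)
      int <- int + stats::rnorm(length(wavelengths), 0, noise@sigmaIntensity)
    emissionSpectrum(wavelengths, int)
  }))
  attr(spectra, "groundTruth") <- .groundTruth("lambdaMaxModel", substrate,
                                               params, noise,
                                               list(truth = mu,
                                                    times = times,
                                                    fwhm = fwhm))
  spectra
}

#' Generate a degree-of-hydrolysis time series
#'
#' Forward-simulates d(t) and adds absolute Gaussian noise of sd
#' \code{sigmaDh}. Optionally also emits synthetic amino-nitrogen (OPA)
#' readings N = N0 + d * deltaN, the inverse of \code{\link{dhFromOpa}}.
#'
#' @inheritParams generateLambdaSeries
#' @param opa optional list with elements \code{N0} and \code{deltaN}; when
#'   given, a column \code{N} of synthetic amino-nitrogen readings is added.
#' @return data.frame with columns \code{t}, \code{d} (and \code{N});
#'   attribute \code{groundTruth}.
#' @export
generateDhSeries <- function(substrate, params, times, noise = noiseSpec(),
                             opa = NULL) {
  mu <- degreeOfHydrolysis(times, substrate, params)
  d <- .withSeed(noise@seed,
                 mu + stats::rnorm(length(times), 0, noise@sigmaDh))
  out <- data.frame(t = times, d = d)
  if (!is.null(opa)) {
    stopifnot(is.numeric(opa$N0), is.numeric(opa$deltaN), opa$deltaN > 0)
    out$N <- opa$N0 + d * opa$deltaN
  }
  attr(out, "groundTruth") <- .groundTruth("degreeOfHydrolysis", substrate,
                                           params, noise,
                                           list(truth = mu, opa = opa))
  out
}
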