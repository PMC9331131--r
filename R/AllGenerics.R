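#' Accessors for model objects
#'
#' Accessor generics for the S4 classes of the package: total bond count,
#' bond classes, pool fractions and fluorescence levels of a
#' \linkS4class{SubstrateModel}; degree-of-hydrolysis, rate and time vectors
#' of a \linkS4class{RateCurve}; and the fitted parameters of a
#' \linkS4class{TailFit} or \linkS4class{SlopeResult}.
#'
#' @param object an object of the documented class.
#' @return The slot value (see the individual generic).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("totalBonds", function(object) standardGeneric("totalBonds"))
#' @rdname accessors
#' @export
setGeneric("bondClasses", function(object) standardGeneric("bondClasses"))
#' @rdname accessors
#' @export
setGeneric("poolFractions", function(object) standardGeneric("poolFractions"))
#' @rdname accessors
#' @export
setGeneric("lambdaLevels", function(object) standardGeneric("lambdaLevels"))
#' @rdname accessors
#' @export
setGeneric("dValues", function(object) standardGeneric("dValues"))
#' @rdname accessors
#' @export
setGeneric("rValues", function(object) standardGeneric("rValues"))
#' @rdname accessors
#' @export
setGeneric("timeValues", function(object) standardGeneric("timeValues"))
#' @rdname accessors
#' @export
setGeneric("lambdaStar", function(object) standardGeneric("lambdaStar"))
#' @rdname accessors
#' @export
setGeneric("tailRate", function(object) standardGeneric("tailRate"))
#' @rdname accessors
#' @export
setGeneric("tailAmplitude", function(object) standardGeneric("tailAmplitude"))
#' @rdname accessors
#' @export
setGeneric("slopeValue", function(object) standardGeneric("slopeValue"))

#' @rdname accessors
setMethod("totalBonds", "SubstrateModel", function(object) object@totalBonds)
#' @rdname accessors
setMethod("bondClasses", "SubstrateModel", function(object) object@classes)
#' @rdname accessors
setMethod("poolFractions", "SubstrateModel", function(object)
  c(s01 = object@s01Fraction, s02 = object@s02Fraction))
#' @rdname accessors
setMethod("lambdaLevels", "SubstrateModel", function(object)
  c(lambda1 = object@lambda1, lambda2 = object@lambda2,
    lambda3 = object@lambda3))
#' @rdname accessors
setMethod("dValues", "RateCurve", function(object) object@d)
#' @rdname accessors
setMethod("rValues", "RateCurve", function(object) object@r)
#' @rdname accessors
setMethod("timeValues", "RateCurve", function(object) object@times)
#' @rdname accessors
setMethod("lambdaStar", "TailFit", function(object) object@lambdaStar)
#' @rdname accessors
setMethod("tailRate", "TailFit", function(object) object@rate)
#' @rdname accessors
setMethod("tailAmplitude", "TailFit", function(object) object@amplitude)
#' @rdname accessors
setMethod("slopeValue", "SlopeResult", function(object) object@b)

setMethod("show", "BondClass", function(object) {
  cat(sprintf("BondClass: %d bond(s), route %s%s\n", object@count,
              object@route,
              if (object@route == "fast") ""
              else sprintf(", kappa = %g", object@kappa)))
})

setMethod("show", "SubstrateModel", function(object) {
  cat(sprintf("SubstrateModel '%s': %d peptide bonds, %d specific in %d class(es)\n",
              object@name, object@totalBonds,
              sum(vapply(object@classes, function(x) x@count, integer(1))),
              length(object@classes)))
  for (cl in object@classes)
    cat("  - ", format(cl@count, width = 2), " x ", cl@route,
        if (cl@route != "fast") sprintf(" (kappa = %g)", cl@kappa) else "",
        "\n", sep = "")
  cat(sprintf("  pool fractions s01 = %.4g, s02 = %.4g; lambda = %g/%g/%g nm\n",
              object@s01Fraction, object@s02Fraction,
              object@lambda1, object@lambda2, object@lambda3))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: k1 = %g, k2 = %g L/mg/min; km = %g 1/min; E = %g, E0 = %g mg/L\n",
              object@k1, object@k2, object@km, object@E, object@E0))
})

setMethod("show", "DimensionlessParams", function(object) {
  cat(sprintf("DimensionlessParams: epsilon = %g, kappaM = %g, kappa2 = %g\n",
              object@epsilon, object@kappaM, object@kappa2))
})

setMethod("show", "RateCurve", function(object) {
  cat(sprintf("RateCurve: %d points, d in [%.4g, %.4g]", length(object@d),
              min(object@d), max(object@d)))
  if (!is.null(object@provenance$r0))
    cat(sprintf(", analytic r0 = %.4g", object@provenance$r0))
  cat("\n")
})

setMethod("show", "SlopeResult", function(object) {
  cat(sprintf("SlopeResult: b = %.3f (SE %.3f) on d in [%g, %g], %d points (%s rates)\n",
              object@b, object@bSE, object@interval[1], object@interval[2],
              object@nPoints, object@rateMethod))
  if (is.finite(object@bAlt))
    cat(sprintf("  alternative rate convention: b = %.3f\n", object@bAlt))
  if (is.finite(object@dStar))
    cat(sprintf("  drop-off d* = %.4f\n", object@dStar))
})

setMethod("show", "TailFit", function(object) {
  if (object@degenerate) {
    cat(sprintf("TailFit (degenerate): constant series, lambda* = %.2f nm, rate unidentifiable\n",
                object@lambdaStar))
  } else {
    cat(sprintf("TailFit: lambda* = %.2f +/- %.2f nm, a = %.2f +/- %.2f nm, k = %.4g +/- %.2g, r^2 = %.4f (n = %d, t >= %.3g)\n",
                object@lambdaStar, object@se["lambdaStar"],
                object@amplitude, object@se["amplitude"],
                object@rate, object@se["rate"], object@rSquared,
                object@n, object@tMin))
  }
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %g-%g nm, peak near %g nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths),
              object@wavelengths[which.max(object@intensities)]))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: sigmaLambda = %g nm, sigmaIntensity = %g, sigmaDh = %g, seed = %d\n",
              object@sigmaLambda, object@sigmaIntensity, object@sigmaDh,
              object@seed))
})
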