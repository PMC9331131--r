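#' @import methods
NULL

.validRoutes <- c("fast", "one_stage", "two_stage")

#' Bond class of a proteolytic substrate
#'
#' A group of specific peptide bonds sharing one demasking route and one
#' relative hydrolysis rate constant. Routes: \code{"fast"} bonds are
#' hydrolyzed as soon as they are demasked (hydrolysis much faster than
#' demasking, single-exponential law, not reduced by secondary masking);
#' \code{"one_stage"} bonds become attackable after a single enzymatic
#' opening of the substrate; \code{"two_stage"} bonds require a second
#' enzymatic opening step before hydrolysis.
#'
#' @slot count integer, number of bonds in the class.
#' @slot kappa numeric, relative hydrolysis rate constant (bond rate constant
#'   over the first-stage demasking rate constant). Ignored for
#'   \code{route = "fast"}.
#' @slot route character, one of \code{"fast"}, \code{"one_stage"},
#'   \code{"two_stage"}.
#' @export
setClass("BondClass",
  representation(count = "integer", kappa = "numeric", route = "character"),
  prototype(count = 0L, kappa = NA_real_, route = "fast"))

setValidity("BondClass", function(object) {
  msg <- character()
  if (length(object@count) != 1L || is.na(object@count) || object@count < 0L)
    msg <- c(msg, "count must be a single nonnegative integer")
  if (length(object@route) != 1L || !object@route %in% .validRoutes)
    msg <- c(msg, sprintf("route must be one of %s",
                          paste(.validRoutes, collapse = ", ")))
  if (object@route %in% c("one_stage", "two_stage") &&
      (length(object@kappa) != 1L || is.na(object@kappa) || object@kappa <= 0))
    msg <- c(msg, "kappa must be > 0 for one_stage/two_stage routes")
  if (length(msg)) msg else TRUE
})

#' Create a bond class
#'
#' @param count number of bonds in the class.
#' @param kappa relative hydrolysis rate constant (ignored for fast bonds).
#' @param route demasking route: \code{"fast"}, \code{"one_stage"} or
#'   \code{"two_stage"}.
#' @return A \linkS4class{BondClass} object.
#' @examples
#' bondClass(4, route = "fast")
#' bondClass(2, kappa = 0.8, route = "one_stage")
#' @export
bondClass <- function(count, kappa = NA_real_, route = c("fast", "one_stage", "two_stage")) {
  route <- match.arg(route)
  new("BondClass", count = as.integer(count), kappa = as.numeric(kappa),
      route = route)
}

#' Proteolytic substrate model
#'
#' Describes a protein substrate for the demasking/secondary-masking
#' proteolysis model: the inventory of specific peptide bonds grouped into
#' \linkS4class{BondClass}es, the fractions of substrate material demasked in
#' one or two stages, and the tryptophan fluorescence maxima of the masked
#' (\code{lambda1}), partially demasked (\code{lambda2}) and fully demasked
#' (\code{lambda3}) states.
#'
#' @slot totalBonds integer, total number of peptide bonds B0 in the substrate.
#' @slot classes list of \linkS4class{BondClass}.
#' @slot s01Fraction numeric, fraction of the substrate pool demasked in one
#'   stage.
#' @slot s02Fraction numeric, fraction demasked in two stages.
#' @slot lambda1,lambda2,lambda3 numeric, fluorescence maxima (nm) of the
#'   masked, partially demasked and fully demasked states.
#' @slot bondAnnotation data.frame, optional named-bond metadata (columns
#'   \code{bond}, \code{route}, \code{kappa}).
#' @slot name character, substrate label.
#' @export
setClass("SubstrateModel",
  representation(totalBonds = "integer", classes = "list",
                 s01Fraction = "numeric", s02Fraction = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
                 bondAnnotation = "data.frame", name = "character"),
  prototype(totalBonds = 0L, classes = list(), s01Fraction = 1,
            s02Fraction = 0, lambda1 = 340, lambda2 = 350, lambda3 = 354,
            bondAnnotation = data.frame(), name = "substrate"))

setValidity("SubstrateModel", function(object) {
  msg <- character()
  if (!all(vapply(object@classes, is, logical(1), "BondClass")))
    msg <- c(msg, "classes must all be BondClass objects")
  else {
    nspec <- sum(vapply(object@classes, function(x) x@count, integer(1)))
    if (object@totalBonds < nspec)
      msg <- c(msg, "totalBonds must be >= the sum of class counts")
  }
  if (abs(object@s01Fraction + object@s02Fraction - 1) > 1e-8)
    msg <- c(msg, "s01Fraction + s02Fraction must equal 1")
  if (object@s01Fraction < 0 || object@s02Fraction < 0)
    msg <- c(msg, "pool fractions must be nonnegative")
  if (!(object@lambda1 <= object@lambda2 && object@lambda2 <= object@lambda3))
    msg <- c(msg, "fluorescence levels must satisfy lambda1 <= lambda2 <= lambda3 (redshift ordering)")
  if (length(msg)) msg else TRUE
})

#' Create a substrate model
#'
#' @param totalBonds total number of peptide bonds B0.
#' @param classes list of \linkS4class{BondClass} objects.
#' @param s01Fraction,s02Fraction substrate pool fractions demasked in one and
#'   two stages (must sum to 1). Default: proportions of bond counts on each
#'   route.
#' @param lambda1,lambda2,lambda3 fluorescence maxima (nm) for the masked,
#'   partially demasked and fully demasked states.
#' @param bondAnnotation optional data.frame of named-bond metadata.
#' @param name substrate label.
#' @return A \linkS4class{SubstrateModel}.
#' @examples
#' substrateModel(161, list(bondClass(15, route = "fast")))
#' @export
substrateModel <- function(totalBonds, classes,
                           s01Fraction = NULL, s02Fraction = NULL,
                           lambda1 = 340, lambda2 = 350, lambda3 = 354,
                           bondAnnotation = data.frame(), name = "substrate") {
  if (is.null(s01Fraction) || is.null(s02Fraction)) {
    cnt <- vapply(classes, function(x) x@count, integer(1))
    two <- vapply(classes, function(x) x@route == "two_stage", logical(1))
    tot <- sum(cnt)
    if (tot == 0L) { s01Fraction <- 1; s02Fraction <- 0 }
    else { s02Fraction <- sum(cnt[two]) / tot; s01Fraction <- 1 - s02Fraction }
  }
  new("SubstrateModel", totalBonds = as.integer(totalBonds), classes = classes,
      s01Fraction = s01Fraction, s02Fraction = s02Fraction,
      lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
      bondAnnotation = bondAnnotation, name = name)
}

#' Dimensional kinetic parameters
#'
#' Rate constants and enzyme concentration for the proteolysis model in
#' laboratory units. The first- and second-stage demasking steps are
#' enzymatic with pseudo-first-order rate constants \code{k1*E} and
#' \code{k2*E}; secondary masking is non-enzymatic with first-order rate
#' constant \code{km}.
#'
#' @slot k1 first-stage demasking rate constant, L mg^-1 min^-1.
#' @slot k2 second-stage demasking rate constant, L mg^-1 min^-1.
#' @slot km secondary masking rate constant, min^-1.
#' @slot E enzyme concentration, mg/L.
#' @slot E0 reference enzyme concentration, mg/L (default 10).
#' @export
setClass("KineticParams",
  representation(k1 = "numeric", k2 = "numeric", km = "numeric",
                 E = "numeric", E0 = "numeric"),
  prototype(k1 = 1, k2 = 0.3, km = 0, E = 10, E0 = 10))

setValidity("KineticParams", function(object) {
  v <- c(k1 = object@k1, k2 = object@k2, km = object@km,
         E = object@E, E0 = object@E0)
  msg <- character()
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "all kinetic parameters must be finite and nonnegative")
  if (object@E0 <= 0) msg <- c(msg, "E0 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create dimensional kinetic parameters
#'
#' @param k1,k2 demasking rate constants (L mg^-1 min^-1).
#' @param km secondary masking rate constant (min^-1).
#' @param E enzyme concentration (mg/L).
#' @param E0 reference enzyme concentration (mg/L).
#' @return A \linkS4class{KineticParams}.
#' @examples
#' kineticParams(k1 = 0.02, k2 = 0.006, km = 0.0015, E = 10)
#' @export
kineticParams <- function(k1, k2 = 0.3 * k1, km = 0, E, E0 = 10) {
  new("KineticParams", k1 = k1, k2 = k2, km = km, E = E, E0 = E0)
}

#' Dimensionless kinetic parameters
#'
#' The reduced parameterization used for model exploration: dimensionless
#' enzyme concentration \code{epsilon} = E/E0, dimensionless secondary
#' masking rate constant \code{kappaM} = km/(k1 E0), and the ratio
#' \code{kappa2} = k2/k1 of the two demasking rate constants. Time enters as
#' the dimensionless variable tau = k1 E0 t (see
#' \code{\link{toDimensionlessTime}}).
#'
#' @slot epsilon dimensionless enzyme concentration (> 0).
#' @slot kappaM dimensionless secondary masking rate constant (>= 0).
#' @slot kappa2 ratio of second- to first-stage demasking rate constants.
#' @export
setClass("DimensionlessParams",
  representation(epsilon = "numeric", kappaM = "numeric", kappa2 = "numeric"),
  prototype(epsilon = 1, kappaM = 0, kappa2 = 0.3))

setValidity("DimensionlessParams", function(object) {
  msg <- character()
  if (!is.finite(object@epsilon) || object@epsilon <= 0)
    msg <- c(msg, "epsilon must be > 0 (an enzyme-free run has no kinetics)")
  if (!is.finite(object@kappaM) || object@kappaM < 0)
    msg <- c(msg, "kappaM must be >= 0")
  if (!is.finite(object@kappa2) || object@kappa2 < 0)
    msg <- c(msg, "kappa2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create dimensionless kinetic parameters
#'
#' @param epsilon dimensionless enzyme concentration E/E0.
#' @param kappaM dimensionless secondary masking rate constant km/(k1 E0).
#' @param kappa2 ratio k2/k1 (default 0.3).
#' @return A \linkS4class{DimensionlessParams}.
#' @examples
#' dimensionlessParams(epsilon = 2, kappaM = 0.05)
#' @export
dimensionlessParams <- function(epsilon, kappaM = 0, kappa2 = 0.3) {
  new("DimensionlessParams", epsilon = epsilon, kappaM = kappaM,
      kappa2 = kappa2)
}

#' Fluorescence emission spectrum
#'
#' @slot wavelengths numeric, strictly increasing wavelengths (nm).
#' @slot intensities numeric, intensities (arbitrary units), same length.
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", intensities = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@intensities))
    msg <- c(msg, "wavelengths and intensities must have the same length")
  if (any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Create an emission spectrum
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param intensities intensities (arbitrary units).
#' @return A \linkS4class{Spectrum}.
#' @export
emissionSpectrum <- function(wavelengths, intensities) {
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      intensities = as.numeric(intensities))
}

#' Parametric hydrolysis-rate curve
#'
#' A trajectory of degree of hydrolysis \code{d} and hydrolysis rate
#' \code{r = dd/dt} with time eliminated, as used for the ln(r)-versus-d
#' analysis. Model-derived curves carry the analytic initial rate in
#' \code{provenance$r0}.
#'
#' @slot times numeric, the (dimensionless or dimensional) time grid.
#' @slot d numeric, degree of hydrolysis, strictly increasing.
#' @slot r numeric, hydrolysis rate, positive where ln r is used.
#' @slot provenance list of metadata (model parameters or series id, analytic
#'   initial rate \code{r0}).
#' @export
setClass("RateCurve",
  representation(times = "numeric", d = "numeric", r = "numeric",
                 provenance = "list"))

setValidity("RateCurve", function(object) {
  msg <- character()
  n <- length(object@d)
  if (length(object@r) != n || length(object@times) != n)
    msg <- c(msg, "times, d and r must have the same length")
  if (n > 1 && any(diff(object@d) <= 0))
    msg <- c(msg, "d must be strictly increasing along the curve")
  if (length(msg)) msg else TRUE
})

#' Slope of the exponential proteolysis model
#'
#' Result of fitting ln(r) = -b d + const over a fixed interval of degree of
#' hydrolysis. \code{bAlt} stores the estimate under the alternative rate
#' convention (analytic versus finite-difference rates at the sample points)
#' as a grid-sensitivity diagnostic.
#'
#' @slot b numeric, negated slope of ln r on d.
#' @slot bSE numeric, standard error of b.
#' @slot intercept numeric, fitted ln(a).
#' @slot interval numeric length-2, fit interval in d.
#' @slot nPoints integer, number of uniform-d sample points.
#' @slot rateMethod character, rate convention used for \code{b}.
#' @slot bAlt numeric, estimate under the alternative rate convention.
#' @slot dStar numeric, drop-off point if attached (NA otherwise).
#' @export
setClass("SlopeResult",
  representation(b = "numeric", bSE = "numeric", intercept = "numeric",
                 interval = "numeric", nPoints = "integer",
                 rateMethod = "character", bAlt = "numeric",
                 dStar = "numeric"),
  prototype(dStar = NA_real_, bAlt = NA_real_))

#' Exponential tail fit of the fluorescence maximum
#'
#' Parameters of the long-time single-exponential approach of the
#' fluorescence maximum to its asymptote: lambda_max(t) = lambda* - a
#' exp(-k t), where k equals the sum of the secondary masking rate constant
#' and the second-stage demasking rate constant (km + k2 E).
#'
#' @slot lambdaStar numeric, asymptotic fluorescence maximum (nm).
#' @slot amplitude numeric, tail amplitude a (nm).
#' @slot rate numeric, tail rate k (min^-1 or dimensionless).
#' @slot se numeric named vector of standard errors.
#' @slot rSquared numeric, goodness of fit.
#' @slot n integer, number of points used.
#' @slot tMin numeric, cutoff time used.
#' @slot degenerate logical, TRUE when the series was constant and the rate
#'   is unidentifiable.
#' @export
setClass("TailFit",
  representation(lambdaStar = "numeric", amplitude = "numeric",
                 rate = "numeric", se = "numeric", rSquared = "numeric",
                 n = "integer", tMin = "numeric", degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("TailFit", function(object) {
  if (!object@degenerate && (!is.finite(object@rate) || object@rate <= 0))
    return("rate must be > 0 for a non-degenerate fit")
  if (is.finite(object@lambdaStar) && !object@degenerate &&
      (object@lambdaStar < 300 || object@lambdaStar > 400))
    return("lambdaStar outside the 300-400 nm sanity band")
  TRUE
})

#' Noise specification for synthetic data
#'
#' @slot sigmaLambda numeric, additive Gaussian noise on lambda_max (nm).
#' @slot sigmaIntensity numeric, additive Gaussian noise on spectral
#'   intensities (relative to unit peak height).
#' @slot sigmaDh numeric, absolute additive Gaussian noise on d.
#' @slot seed integer seed; identical seed and configuration give identical
#'   output.
#' @export
setClass("NoiseSpec",
  representation(sigmaLambda = "numeric", sigmaIntensity = "numeric",
                 sigmaDh = "numeric", seed = "integer"),
  prototype(sigmaLambda = 0.2, sigmaIntensity = 0.01, sigmaDh = 0.001,
            seed = 1L))

setValidity("NoiseSpec", function(object) {
  if (any(c(object@sigmaLambda, object@sigmaIntensity, object@sigmaDh) < 0))
    return("noise sigmas must be >= 0")
  TRUE
})

#' Create a noise specification
#'
#' @param sigmaLambda additive Gaussian sd on lambda_max, nm. The default
#'   0.2 nm makes tail-fit standard errors on lambda* of a few tenths of a
#'   nanometre emerge at about 30 points per series.
#' @param sigmaIntensity additive Gaussian sd on spectral intensities,
#'   relative to a unit peak.
#' @param sigmaDh absolute Gaussian sd on the degree of hydrolysis.
#' @param seed integer seed.
#' @return A \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(sigmaLambda = 0.2, sigmaIntensity = 0.01,
                      sigmaDh = 0.001, seed = 1L) {
  new("NoiseSpec", sigmaLambda = sigmaLambda, sigmaIntensity = sigmaIntensity,
      sigmaDh = sigmaDh, seed = as.integer(seed))
}
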