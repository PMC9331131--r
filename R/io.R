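## Configuration, tabular I/O and the command-style pipeline entry points.
## CSV dialect: comma-separated, dot decimal, mandatory header; units are
## encoded in the column names (t_min, lambda_max_nm, d, r_per_tau).

#' Read a run configuration
#'
#' Reads a YAML (or JSON) run configuration describing the substrate, the
#' kinetic parameters (exactly one of a \code{dimensional} or
#' \code{dimensionless} block) and analysis options. The packaged default
#' configuration for tryptic proteolysis of beta-lactoglobulin is at
#' \code{system.file("extdata", "beta_lg_trypsin.yaml", package =
#' "DemaskingKinetics")}.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks the configuration schema before any computation and reports all
#' violations at once.
#'
#' @param cfg configuration list.
#' @return Invisibly TRUE; stops with an itemized message on violations.
#' @export
validateRunConfig <- function(cfg) {
  errs <- character()
  if (is.null(cfg$substrate)) {
    errs <- c(errs, "missing 'substrate' block")
  } else {
    s <- cfg$substrate
    if (is.null(s$total_bonds)) errs <- c(errs, "substrate: missing total_bonds")
    if (is.null(s$classes) || !length(s$classes))
      errs <- c(errs, "substrate: missing bond classes")
    else for (i in seq_along(s$classes)) {
      cl <- s$classes[[i]]
      if (is.null(cl$route) || !cl$route %in% .validRoutes)
        errs <- c(errs, sprintf("substrate class %d: route must be one of %s",
                                i, paste(.validRoutes, collapse = ", ")))
      if (is.null(cl$count))
        errs <- c(errs, sprintf("substrate class %d: missing count", i))
      if (!identical(cl$route, "fast") && is.null(cl$kappa))
        errs <- c(errs, sprintf("substrate class %d: missing kappa", i))
    }
  }
  hasDim <- !is.null(cfg$kinetics$dimensional)
  hasDml <- !is.null(cfg$kinetics$dimensionless)
  if (hasDim + hasDml != 1L)
    errs <- c(errs, "kinetics: exactly one of 'dimensional' or 'dimensionless' must be present")
  if (hasDml) {
    dl <- cfg$kinetics$dimensionless
    if (is.null(dl$epsilon)) errs <- c(errs, "kinetics$dimensionless: missing epsilon")
    else if (dl$epsilon <= 0) errs <- c(errs, "kinetics$dimensionless: epsilon must be > 0")
  }
  if (hasDim) {
    dm <- cfg$kinetics$dimensional
    for (f in c("k1", "E"))
      if (is.null(dm[[f]])) errs <- c(errs, sprintf("kinetics$dimensional: missing %s", f))
  }
  if (length(errs))
    stop("invalid run configuration:\n", paste("  -", errs, collapse = "\n"))
  invisible(TRUE)
}

#' Build model objects from a configuration
#'
#' @param cfg a validated configuration list (see \code{\link{readRunConfig}}).
#' @return \code{substrateFromConfig}: a \linkS4class{SubstrateModel};
#'   \code{paramsFromConfig}: a \linkS4class{KineticParams} or
#'   \linkS4class{DimensionlessParams}.
#' @export
substrateFromConfig <- function(cfg) {
  s <- cfg$substrate
  classes <- lapply(s$classes, function(cl)
    bondClass(cl$count, kappa = if (is.null(cl$kappa)) NA_real_ else cl$kappa,
              route = cl$route))
  lam <- s$lambda
  ann <- if (!is.null(s$bond_annotation))
    do.call(rbind, lapply(s$bond_annotation, function(x)
      data.frame(bond = x$bond, route = x$route,
                 kappa = if (is.null(x$kappa)) NA_real_ else x$kappa)))
  else data.frame()
  substrateModel(
    totalBonds = s$total_bonds, classes = classes,
    s01Fraction = s$s01_fraction, s02Fraction = s$s02_fraction,
    lambda1 = if (is.null(lam$masked)) 340 else lam$masked,
    lambda2 = if (is.null(lam$partial)) 350 else lam$partial,
    lambda3 = if (is.null(lam$demasked)) 354 else lam$demasked,
    bondAnnotation = ann,
    name = if (is.null(s$name)) "substrate" else s$name)
}

#' @rdname substrateFromConfig
#' @export
paramsFromConfig <- function(cfg) {
  if (!is.null(cfg$kinetics$dimensionless)) {
    dl <- cfg$kinetics$dimensionless
    dimensionlessParams(epsilon = dl$epsilon,
                        kappaM = if (is.null(dl$kappa_m)) 0 else dl$kappa_m,
                        kappa2 = if (is.null(dl$kappa2)) 0.3 else dl$kappa2)
  } else {
    dm <- cfg$kinetics$dimensional
    kineticParams(k1 = dm$k1,
                  k2 = if (is.null(dm$k2)) 0.3 * dm$k1 else dm$k2,
                  km = if (is.null(dm$km)) 0 else dm$km,
                  E = dm$E,
                  E0 = if (is.null(dm$E0)) 10 else dm$E0)
  }
}

#' Read and write spectrum and time-series CSV files
#'
#' \code{readSpectrumCsv}/\code{writeSpectrumCsv} use columns
#' \code{wavelength_nm}, \code{intensity}; \code{readTimeSeriesCsv} expects a
#' \code{t_min} column plus the named value column (default
#' \code{lambda_max_nm}). Malformed files produce errors naming the file and
#' the missing columns.
#'
#' @param path CSV file path.
#' @param spectrum a \linkS4class{Spectrum} (for writing).
#' @param valueColumn value column name for time series.
#' @return A \linkS4class{Spectrum} or a data.frame.
#' @export
readSpectrumCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "intensity")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  emissionSpectrum(df$wavelength_nm, df$intensity)
}

#' @rdname readSpectrumCsv
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelengths,
                              intensity = spectrum@intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname readSpectrumCsv
#' @export
readTimeSeriesCsv <- function(path, valueColumn = "lambda_max_nm") {
  df <- utils::read.csv(path)
  need <- c("t_min", valueColumn)
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  df
}

#' Export model trajectories as CSV
#'
#' Writes the substrate-pool and degree-of-hydrolysis trajectories with
#' columns \code{t_or_tau}, \code{Sm1}, \code{Sd1}, \code{Sm2}, \code{Sd2},
#' \code{Sdd2}, \code{d}.
#'
#' @param times time grid.
#' @param substrate a \linkS4class{SubstrateModel}.
#' @param params parameter object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTrajectoryCsv <- function(times, substrate, params, path) {
  p1 <- oneStagePools(times, params, s01 = substrate@s01Fraction)
  p2 <- twoStagePools(times, params, s02 = substrate@s02Fraction)
  df <- data.frame(t_or_tau = times, Sm1 = p1$Sm1, Sd1 = p1$Sd1,
                   Sm2 = p2$Sm2, Sd2 = p2$Sd2, Sdd2 = p2$Sdd2,
                   d = degreeOfHydrolysis(times, substrate, params))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.resolvedConfigLog <- function(cfg, extras = list()) {
  c(list(package = "DemaskingKinetics",
         version = as.character(utils::packageVersion("DemaskingKinetics")),
         config = cfg), extras)
}

#' Run a model simulation from a configuration
#'
#' Simulates the configured model and writes \code{trajectory.csv} (pools
#' and d), \code{rate_curve.csv} (d, r, ln r) and \code{summary.json}
#' (slope b with standard error, drop-off d*, asymptotic degree of
#' hydrolysis, tail asymptote lambda*, and the resolved configuration).
#' Outputs are deterministic for a given configuration.
#'
#' @param config configuration list or path to a YAML/JSON file.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
runSimulation <- function(config, outDir) {
  cfg <- if (is.character(config)) readRunConfig(config) else {
    validateRunConfig(config); config
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  substrate <- substrateFromConfig(cfg)
  params <- paramsFromConfig(cfg)
  curve <- hydrolysisRate(substrate = substrate, params = params)
  writeTrajectoryCsv(curve@times, substrate, params,
                     file.path(outDir, "trajectory.csv"))
  utils::write.csv(data.frame(d = curve@d, r_per_tau = curve@r,
                              ln_r = log(curve@r)),
                   file.path(outDir, "rate_curve.csv"), row.names = FALSE)
  interval <- if (!is.null(cfg$analysis$fit_interval))
    as.numeric(cfg$analysis$fit_interval) else c(0, 0.05)
  sb <- slopeB(curve, interval = interval)
  ds <- dStar(curve)
  dInf <- degreeOfHydrolysis(max(curve@times), substrate, params)
  tp <- tailParameters(substrate, params)
  summary <- list(b = sb@b, b_se = sb@bSE, b_alt = sb@bAlt, d_star = ds,
                  d_inf = dInf, lambda_star = tp$lambdaStar,
                  tail_rate = tp$rate,
                  log = .resolvedConfigLog(cfg))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Fit fluorescence tail series from CSV files
#'
#' Applies \code{\link{fitTail}} to each series (CSV with columns
#' \code{t_min}, \code{lambda_max_nm}, optionally an enzyme concentration
#' column \code{E_mg_l} or per-file \code{E} in names) and, when two or more
#' distinct enzyme concentrations are present, appends the k = km + k2 E
#' regression.
#'
#' @param paths character vector of CSV paths; names may give the enzyme
#'   concentration (mg/L) per file.
#' @param outPath optional path for a JSON report.
#' @param tMin optional cutoff passed to \code{\link{fitTail}}.
#' @return list with per-series \code{fits} (data.frame) and, when
#'   available, the \code{titration} regression from
#'   \code{\link{estimateKmK2}}.
#' @export
runTailFits <- function(paths, outPath = NULL, tMin = NULL) {
  rows <- lapply(seq_along(paths), function(i) {
    df <- readTimeSeriesCsv(paths[i])
    fit <- fitTail(df$t_min, df$lambda_max_nm, tMin = tMin)
    E <- if (!is.null(df$E_mg_l)) df$E_mg_l[1]
         else if (!is.null(names(paths))) suppressWarnings(as.numeric(names(paths)[i]))
         else NA_real_
    data.frame(series = basename(paths[i]), E = E,
               lambda_star = fit@lambdaStar,
               lambda_star_se = fit@se[["lambdaStar"]],
               k = fit@rate, k_se = fit@se[["rate"]],
               r2 = fit@rSquared, n = fit@n)
  })
  fits <- do.call(rbind, rows)
  out <- list(fits = fits)
  okE <- is.finite(fits$E)
  if (length(unique(fits$E[okE])) >= 2L)
    out$titration <- estimateKmK2(fits$E[okE], fits$k[okE])[
      c("km", "k2", "ratio", "kmSE", "k2SE", "ratioSE")]
  if (!is.null(outPath)) {
    rep <- out
    rep$log <- .resolvedConfigLog(list(paths = unname(paths)))
    jsonlite::write_json(rep, outPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", force = TRUE)
  }
  out
}

#' Generate synthetic fixture files
#'
#' Writes a synthetic fluorescence-maximum series, a degree-of-hydrolysis
#' series (with OPA readings) and a series of emission spectra in the CSV
#' dialects consumed by the fitting functions, together with a
#' \code{manifest.json} listing files, seeds, ground truth and checksums.
#' Identical configuration and seed give identical files.
#'
#' @param config configuration list or path (substrate + kinetics blocks; an
#'   optional \code{synth} block sets \code{times}, \code{noise} sigmas and
#'   \code{seed}).
#' @param outDir output directory.
#' @return Invisibly, the manifest list.
#' @export
runSynth <- function(config, outDir) {
  cfg <- if (is.character(config)) readRunConfig(config) else {
    validateRunConfig(config); config
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  substrate <- substrateFromConfig(cfg)
  params <- paramsFromConfig(cfg)
  sy <- cfg$synth
  times <- if (!is.null(sy$times)) as.numeric(sy$times) else seq(0, 200, by = 5)
  ns <- noiseSpec(
    sigmaLambda = if (is.null(sy$sigma_lambda)) 0.2 else sy$sigma_lambda,
    sigmaIntensity = if (is.null(sy$sigma_intensity)) 0.01 else sy$sigma_intensity,
    sigmaDh = if (is.null(sy$sigma_dh)) 0.001 else sy$sigma_dh,
    seed = if (is.null(sy$seed)) 1L else sy$seed)

  lam <- generateLambdaSeries(substrate, params, times, ns)
  lamPath <- file.path(outDir, "lambda_series.csv")
  utils::write.csv(data.frame(t_min = lam$t, lambda_max_nm = lam$lambda_max),
                   lamPath, row.names = FALSE)

  dh <- generateDhSeries(substrate, params, times, ns,
                         opa = list(N0 = 0.1, deltaN = 2))
  dhPath <- file.path(outDir, "dh_series.csv")
  utils::write.csv(data.frame(t_min = dh$t, d = dh$d, N = dh$N),
                   dhPath, row.names = FALSE)

  spTimes <- times[seq(1, length(times), length.out = min(6, length(times)))]
  spectra <- generateSpectraSeries(substrate, params, spTimes, ns)
  spPaths <- vapply(seq_along(spectra), function(i) {
    p <- file.path(outDir, sprintf("spectrum_%02d.csv", i))
    writeSpectrumCsv(spectra[[i]], p)
    p
  }, character(1))

  files <- c(lamPath, dhPath, spPaths)
  manifest <- list(
    files = basename(files),
    checksums = as.list(tools::md5sum(files)),
    seed = ns@seed,
    noise = list(sigma_lambda = ns@sigmaLambda,
                 sigma_intensity = ns@sigmaIntensity, sigma_dh = ns@sigmaDh),
    ground_truth = list(
      times = times,
      lambda_true_values = attr(lam, "groundTruth")$truth,
      dh_true_values = attr(dh, "groundTruth")$truth,
      spectrum_true_peaks = attr(spectra, "groundTruth")$truth,
      spectrum_times = spTimes),
    log = .resolvedConfigLog(cfg))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the slope/drop-off sweep and write its table
#'
#' Convenience wrapper around \code{\link{rateSummarySweep}} writing the
#' summary as CSV (columns \code{kappa_m}, \code{epsilon}, \code{b},
#' \code{b_se}, \code{d_star}).
#'
#' @param outPath output CSV path.
#' @param ... passed to \code{\link{rateSummarySweep}}.
#' @return The sweep data.frame, invisibly.
#' @export
runRateSweep <- function(outPath, ...) {
  tab <- rateSummarySweep(...)
  utils::write.csv(tab, outPath, row.names = FALSE)
  invisible(tab)
}
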