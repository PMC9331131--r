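# Shared fixtures: default substrate, parameter sets, and a tiny
# random-parameter sampler for property-style tests.

defaultSub <- function() betaLgSubstrate()

# substrate with a single fast class: d(tau) = (n/B0) (1 - exp(-eps tau)),
# the single-exponential reference case of 15 identical, fully demasked bonds
identicalBondSub <- function(n = 15L, B0 = 161L)
  substrateModel(B0, list(bondClass(n, route = "fast")))

# one-stage-only substrate (no two-stage pool)
oneStageOnlySub <- function()
  substrateModel(161L, list(bondClass(4, route = "fast"),
                            bondClass(6, kappa = 0.5, route = "one_stage")))

# log-uniform random rate draws for oracle-equivalence checks
drawParams <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  kineticParams(k1 = lu(0.005, 0.5), k2 = lu(0.001, 0.5),
                km = lu(1e-4, 0.1), E = lu(0.5, 20), E0 = 10)
}

# tail-fit parameter sets from the published enzyme titration of beta-LG and
# beta-CN (lambda* nm, k min^-1); used as synthetic-generator ground truths
tailParamSets <- function() data.frame(
  substrate = c("beta-LG", "beta-LG", "beta-LG", "beta-CN", "beta-CN", "beta-CN"),
  E = c(15, 4.5, 0.9, 2.5, 0.5, 0.25),
  lambdaStar = c(353.7, 352.0, 344.6, 357.8, 356.8, 356.4),
  k = c(0.065, 0.019, 0.006, 0.15, 0.040, 0.023))
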