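Package: DemaskingKinetics
Title: Proteolysis Kinetics with Peptide-Bond Demasking and Secondary Masking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-form kinetic modelling of limited proteolysis in which
    peptide bonds become accessible to the protease through one-stage or
    two-stage demasking of the substrate while intermediate polypeptides
    undergo non-enzymatic secondary masking. Provides multi-exponential
    solutions for substrate pools and per-bond cleavage products, the
    tryptophan fluorescence redshift observable and its single-exponential
    long-time tail, degree-of-hydrolysis trajectories in dimensional or
    dimensionless form, rate-versus-hydrolysis-degree analysis (exponential
    slope b and the rate drop-off point d*), nonlinear tail fitting with
    enzyme-titration regression for the masking and demasking rate constants,
    parabolic localization of emission peaks, and seeded synthetic-data
    generators for spectra, fluorescence-maximum series and degree-of-
    hydrolysis series. A numerical ODE oracle validates every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
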