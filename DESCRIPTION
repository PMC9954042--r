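Package: ultrafastSpec
Title: Global and Target Analysis of Ultrafast Transient Absorption and
    Stimulated Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved spectroscopy of photoactive proteins and
    chromophores: compartmental photocycle models with analytic Gaussian
    instrument-response convolution, variable-projection global analysis of
    femtosecond transient-absorption matrices returning evolution- and
    decay-associated difference spectra (EADS/DADS) with model-order scanning,
    IRF-convolved multi-exponential fitting of probe-band time traces,
    femtosecond stimulated Raman (FSRS) axis conventions, spline baseline
    subtraction, Gaussian peak fitting and marker-band dynamics, steady-state
    band metrics (Stokes shifts, isosbestic points, two-state titration fits),
    and a synthetic-data generator emulating the photocycles of a green-red
    calcium biosensor for end-to-end testing without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
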