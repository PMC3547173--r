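Package: cmcfield
Title: Canonical-Microcircuit Neural-Field Models of Gamma-Band Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical generative modelling of single-channel MEG/EEG
    power spectra with a four-population canonical-microcircuit neural
    field.  Laminar neural-mass dynamics are coupled by exponential and
    patchy lateral connectivity kernels with conduction delays; the
    linearised transfer function, a Gaussian lead field and parameterised
    input/channel-noise spectra yield predicted gamma-band (30-80 Hz)
    auto-spectra.  Models are inverted by variational Laplace
    (Gauss-Newton ascent on free energy) giving posterior densities over
    log-scaling parameters and an evidence bound for field-versus-mass
    model comparison.  Includes synthetic-data generators (spectra,
    linearised time series, correlated group datasets), gamma-peak
    extraction, and population-level statistics: correlation and partial
    correlation tests and maximum-likelihood path analysis (SEM) with AIC
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
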