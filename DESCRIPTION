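Package: svcycle
Title: Population Imaging Analysis of Synaptic Vesicle Cycling and
    Presynaptic Calcium Channel Currents
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population imaging of the synaptic vesicle cycle with
    pHluorin-based reporters and vesicle-targeted calcium sensors.  Segments
    responsive presynaptic boutons from dF response maps of time-lapse stacks,
    re-aligns stage drift, extracts NH4Cl-normalized per-bouton traces,
    decomposes exo- and endocytic components using bafilomycin protocols, and
    estimates rates by windowed linear fits.  Statistical inference on
    bouton-level outcomes respects intra-field clustering through a linear
    mixed model with random field effects and preparation fixed effects
    (REML, profiled variance ratio), with field-averaging and naive pooled
    comparators.  Includes Boltzmann fitting of current-voltage and
    tail-current activation data from voltage-clamp experiments, and a
    forward simulator that renders fluorescence movies and current sweeps
    with known ground truth so that every stage of the pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
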