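Package: oscgrid
Title: Oscillatory-Interference Grid Cell Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a medial entorhinal grid cell as a leaky
    integrate-and-fire neuron summing half-wave-rectified input from six
    phase-offset head-direction band-cell populations acting as
    velocity-controlled oscillators, and provides the accompanying analysis
    pipeline: random-walk and straight-line trajectory generation, bootstrap
    in-field/out-of-field classification, DC-shift and theta-envelope
    decomposition of the membrane potential, theta phase precession with
    circular-linear correlation, spatial rate maps and gridness scoring,
    firing-rate correlations, Steiger's test for dependent correlations, and
    mutual information between membrane-potential amplitudes and field index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'band.R'
    'experiment.R'
    'gridcell.R'
    'precession.R'
    'protocols.R'
    'signalproc.R'
    'spatial.R'
    'statscorr.R'
    'trajectory.R'
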