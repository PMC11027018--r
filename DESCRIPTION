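Package: etsim
Title: Coupled Endothelin-1 Kinetics and Cardiorenal Physiology Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the integrated cardiovascular and renal response to
    endothelin-1 (ET-1) in healthy humans by coupling a two-compartment model
    of ET-1 kinetics, receptor binding and competitive antagonism with a
    reduced ordinary-differential-equation model of renal hemodynamics,
    segmental sodium and water handling, and blood-pressure control.
    Receptor-occupancy-to-effect link functions (linear and sigmoidal),
    clinical infusion protocols for ET-1 and the receptor antagonists BQ123,
    BQ788 and VML588, bounded least-squares calibration, and a forward
    selection / backward elimination procedure for identifying which
    receptor-mediated mechanisms are needed to explain observed hemodynamic
    and excretory responses. Includes a synthetic observation generator for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'etsim-package.R'
    'config.R'
    'effects.R'
    'model.R'
    'kinetics.R'
    'cardiorenal.R'
    'protocols.R'
    'simulate.R'
    'observations.R'
    'objective.R'
    'fit.R'
    'select.R'
    'synthetic.R'
    'cli.R'
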