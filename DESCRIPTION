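Package: vitriqc
Title: Biophysical Quality Control for Membrane-Protein Cryo-EM Sample
    Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the biophysical screening of purified
    membrane-protein samples ahead of electron cryo-microscopy grid
    preparation.  Implements mass-photometry event analysis
    (contrast-to-mass calibration, left-truncated multi-Gaussian fitting
    of mass histograms, oligomeric-state assignment), nanoDSF thermal
    ramp analysis (melting temperatures from the first-derivative
    extremum of the F350/F330 ratio, scattering-based aggregation onset),
    dynamic light scattering analysis (cumulant fits, regularized
    inversion of the intensity autocorrelation into a hydrodynamic-radius
    distribution, Stokes-Einstein conversion, empirical radius-mass
    power law), seeded synthetic-data generators with known ground
    truth, and a combined go/no-go quality-control report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    pracma,
    jsonlite
Suggests:
    rhdf5,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
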