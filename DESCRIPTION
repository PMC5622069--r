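Package: quatMS
Title: Quaternary Structure and Metal Stoichiometry from Native Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the subunit stoichiometry, connectivity and
    metal load of intact protein complexes from native mass spectrometry.
    Implements charge-state assignment and neutral-mass estimation for
    isotope-unresolved charge envelopes, integer composition solving against a
    subunit and adduct catalog, surface-induced dissociation (SID) based
    topology elimination by scoring candidate arrangements against observed
    subcomplexes, metal-adduct satellite series analysis for per-subunit
    occupancy, and power-law collision cross-section calibration for
    travelling-wave ion mobility. A synthetic-data module generates charge
    envelopes, dissociation tables and calibrant sets from a configurable
    ground truth so the whole chain is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'peaks-io.R'
    'deconvolution.R'
    'stoichiometry.R'
    'topology.R'
    'ccs-calibration.R'
    'synthetic-data.R'
    'mnx.R'
    'pipeline.R'
    'quatMS-package.R'
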