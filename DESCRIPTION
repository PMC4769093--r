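Package: amyloidIMS
Title: Amyloid Oligomer and Inhibitor Screening by ESI-IMS-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing native electrospray ionisation ion-mobility
    mass spectrometry (ESI-IMS-MS) screens of amyloid peptide aggregation and
    its inhibition by small molecules. Assigns centroided peaks to peptide
    oligomer, charge and ligand-adduct species (resolving m/z-degenerate ions
    by drift time), estimates collision cross sections by travelling-wave
    power-law calibration, fits and compares isotropic, linear and spherical
    oligomer growth models, and classifies compound binding modes as specific,
    non-specific, colloidal or negative from ligand-adduct stoichiometry
    distributions. Includes a synthetic-spectrum generator so every stage of
    the pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
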