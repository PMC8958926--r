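Package: nscmigrate
Title: Agent-Based Simulation of Neural Stem Cell Migration in Anisotropic
    Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the tumor-tropic migration of therapeutic neural stem
    cells (NSCs) through brain tissue. Local tissue orientation and the
    white/grey matter classification are derived from structure-tensor
    analysis of a scalar image volume (or from a precomputed tensor field);
    agents follow white-matter tracts with inertia, perform isotropic random
    walks in grey matter, and climb an analytic chemoattractant (uPA)
    gradient centred on one or more tumor sites. Migration speed and
    chemosensitivity are heterogeneous across the population via beta-law
    traits. Includes synthetic tissue phantoms (straight, curved and crossing
    tracts in an elliptical brain mask) for fully reproducible scenarios,
    readout metrics (migration distance, white-matter occupancy, tumor
    arrival percentage), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    data.table,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
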