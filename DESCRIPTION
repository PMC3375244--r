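Package: eemr
Title: Electronegativity Equalization Charges for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes empirical partial atomic charges for protein 3D
    structures with the electronegativity equalization method (EEM):
    assembles and solves the constrained linear system coupling atomic
    charges to the equalized molecular electronegativity, calibrates
    per-atom-type model parameters (A, B) and the electrostatic scaling
    factor k against reference charge sets by least squares and grid
    search, validates models with per-molecule correlation and deviation
    statistics, and quantifies per-residue charge transfer between two
    conformations of the same protein. Includes a synthetic reference-set
    generator with a known forward model for testing, and a command-line
    interface for the calibration and profiling workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
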