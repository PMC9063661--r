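Package: lieaffinity
Title: Linear Interaction Energy Analysis of Ligand Binding to Amyloid-Beta Protofibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-point binding free energy analysis with the linear interaction
    energy (LIE) model for inhibitors of amyloid-beta protofibrils. Reads and
    averages ligand-surroundings van der Waals and electrostatic interaction
    energy time series from bound and free-state simulations, fits and applies
    the three-parameter LIE regression, validates predictions against
    experimental affinities, and compares prediction accuracy across end-point
    methods. Also provides a desk-scale pairwise Lennard-Jones/Coulomb energy
    kernel, Kabsch-superposed C-alpha RMSD, geometric hydrogen-bond detection,
    hydrophobic non-bonded contact counting, and a synthetic-data generator so
    the whole pipeline is testable without molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
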