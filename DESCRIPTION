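Package: poremap
Title: Spatial Heat Maps of Molecular Importance from MD Trajectories of Liquids
Version: 0.1.0
Authors@R: person("poremap", "maintainers", email = "poremap@example.org",
    role = c("aut", "cre"))
Description: Transforms time-domain molecular dynamics trajectory data of
    liquid systems (lipid bilayers, solvent) into spatial heat maps that rank
    the importance of individual molecules for a global activity, such as the
    contact-breaking rate of a distance-cutoff graph or a deforming unit-cell
    dimension during electropore formation. Provides periodic-boundary
    distance geometry, two-cutoff hysteresis event detection, Gaussian event
    rate smoothing, Pearson and adaptive-bandwidth kernel mutual information
    bridging of fast pairwise distance rates with the slow activity, column
    compression of the dependence matrix to per-residue heat values, a seeded
    synthetic pore-formation generator, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
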