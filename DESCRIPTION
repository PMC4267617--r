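Package: ionscape
Title: Ion Atmosphere Analysis Around Nucleic Acid Duplexes
Version: 0.1.0
Authors@R:
    person("A.", "Rivera", email = "arivera@example.org", role = c("aut", "cre"))
Description: Analysis of the mobile-ion atmosphere around DNA and RNA duplexes
    from molecular dynamics style trajectories: cylindrical distribution
    functions of ion concentration around the fitted helical axis, radial
    distribution functions around duplex atoms, cumulative charge
    neutralization profiles, binding-site occupancy, residence-time kinetics
    from occupancy autocorrelation, multi-atom binding-pocket detection,
    Einstein diffusion coefficients, and per-residue conformational
    descriptors (glycosidic angle, sugar pucker pseudorotation). Includes a
    synthetic-data module with an idealized B/A/Z duplex builder and
    stochastic ion simulators (telegraph binding, Brownian dynamics,
    hydration-shell sampling) so every estimator is testable by parameter
    recovery against known ground truth. Reads and writes multi-model PDB and
    per-frame XYZ trajectories with periodic box information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
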