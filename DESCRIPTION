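Package: nuctraj
Title: Nucleosome Molecular Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of molecular dynamics trajectories of the nucleosome
    core particle: structure and trajectory input/output with chain, tail,
    domain and superhelix-location (SHL) annotations; histone tail
    truncation; Kabsch least-squares superposition, RMSD time series,
    fluctuation (B-factor) profiles and the truncated-versus-intact order
    parameter R_T; Kabsch-Sander hydrogen-bond secondary-structure
    assignment and helix propensity; DNA backbone dihedrals with BI/BII
    classification, El Hassan-Calladine groove widths and base-pair step
    parameters; hydrogen-bond, minimum-distance, contact-map, detachment
    and pairwise nonbonded interaction-energy analysis; Ewald-smoothed
    electrostatic potential grids; and a seeded synthetic trajectory
    generator (ideal peptides, B-DNA, a nucleosome-like toy system,
    stationary harmonic fluctuations and controlled destabilization
    events) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
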