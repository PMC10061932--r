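Package: psurftools
Title: Trajectory Analysis for Protein-Containing Lipid Monolayer Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics simulations of
    pulmonary-surfactant-like lipid monolayers with embedded hydrophobic
    proteins. Extracts surface pressure-area isotherms from pressure-tensor
    time series, detects liquid-condensed chain packing with a
    periodic-boundary DBSCAN, profiles phase composition and chain tilt
    around proteins, builds phosphorus-aligned transverse density maps with
    5%-of-maximum extent curves, counts and normalizes heavy-atom
    lipid-protein contacts, and estimates lateral diffusion coefficients
    from displacement distributions. A synthetic-configuration generator
    with planted ground truth (hexagonally packed condensed patches,
    protein depletion halos, Brownian motion with known diffusion
    coefficient, scheduled surface-tension series) makes every stage
    verifiable without large trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
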