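Package: porepass
Title: Pore Geometry, Ion Permeation, and Single-Channel Analysis for
    Mechanosensitive Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for mechanosensitive ion channels
    of the MscS/MSL family. Computes sphere-probe radius and hydrophobicity
    profiles along the central pore and the cytoplasmic side portals of a
    channel structure (PDB/mmCIF), per structure or per trajectory frame;
    detects ion permeation events (portal -> cytoplasmic cage -> pore ->
    extracellular bulk) in coordinate trajectories and estimates conductance
    by G = Q/(t x V); and implements single-channel electrophysiology
    analysis: Goldman-Hodgkin-Katz permeability ratios and reversal
    potentials, leak subtraction, Gaussian amplitude-histogram fitting,
    linear-regression slope conductance, and exponential deactivation
    kinetics. Seeded synthetic-data generators (toy channel solids with
    analytic radius profiles, Brownian ion trajectories with ground-truth
    passage logs, Markov-gating patch-clamp sweeps) provide fully
    controlled inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
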