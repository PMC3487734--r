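Package: memhelix
Title: Membrane-Bound Helical Peptide and Bilayer Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics ensembles of amphipathic helical
    peptides bound to lipid bilayers, built around the membrane-bound islet
    amyloid polypeptide (IAPP) 1-25 fragment and DOPC/DOPS slab bilayers.
    Provides a light topology/trajectory data model with periodic-boundary
    geometry; backbone dihedrals, simplified Kabsch-Sander secondary
    structure and per-residue helicity; interhelical (kink) angle series,
    10-degree histograms and conformational-family classification; side-chain
    immersion depth relative to the phosphate plane; Kabsch superposition and
    RMSD; hydrogen-bond and side-chain contact occupancy with block-averaged
    time series; Karplus 3J(HN-HA) coupling prediction and secondary
    chemical-shift comparison; grid-based area per lipid and bilayer
    thickness, acyl-chain deuterium order parameters, and radial distribution
    functions with coordination numbers; plus seeded generators for ideal and
    kinked helices, slab pseudo-bilayers with water and counterions, and
    peptide embedding at a stated depth and orientation, so every analysis
    can be verified against constructed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
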