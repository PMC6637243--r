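Package: glycopucker
Title: Ring-Puckering Analysis of Glycoside Hydrolase Enzyme:Substrate Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for studying carbohydrate ring distortion in
    glycoside hydrolase active sites. Computes Cremer-Pople puckering
    coordinates for pyranose rings, classifies them against the 38 canonical
    six-membered-ring conformers, turns per-frame conformer streams from
    molecular dynamics trajectories into occupancy tables, equatorial
    excursion segmentations and ALPH-compatible conformational itinerary
    assignments, profiles per-subsite flexibility by RMSD after protein-frame
    superposition, evaluates docking poses against reference complexes to
    select molecular dynamics starting coordinates, and builds clan-level
    structural distance trees from symmetrized MaxSub scores by
    neighbor-joining. A synthetic-data module generates ideal rings,
    stochastic puckering trajectories along programmed itineraries and mock
    enzyme:ligand complexes as multi-model PDB, standing in for the docking
    and MD engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
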