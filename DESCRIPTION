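Package: hydropatch
Title: Hydration-Site Patches and Docking-Pose Triage for Protein
    Interface Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein binding interfaces by two
    independent routes. The first triages flexible-docking pose sets by
    steric clash testing, van der Waals contact criteria against
    experimentally implicated residues, and median-split selection over
    seven contact and score metrics, producing pose RMSD matrices and
    contact-pair frequency tables. The second identifies easily
    desolvated "hydration patches" on protein surfaces: hydration sites
    are picked from water ensembles by greedy density maxima, scored
    with per-site inhomogeneous fluid solvation theory (IFST) energy and
    entropy terms, filtered by ion-channel pore geometry, and assembled
    by an exact combinatoric search for the best connected clusters of
    7-18 sites followed by a clustering of clusters into patches. A
    synthetic-data generator with planted ground truth (dock sets, water
    ensembles with attractive wells) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
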