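Package: juncgraph
Title: Coarse-Grained Tree-Graph Modelling of RNA Junction Topology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the helical topology (coaxial stacking pattern and
    junction family) of RNA three- and four-way junctions from secondary
    structure using a random-forest classifier, builds scaled planar tree
    graphs that embody the predicted topology using knowledge-based
    distance parameters derived from solved structures, translates solved
    3D structures (PDB/mmCIF) into the same graph representation, and
    scores predicted against native graphs with RMSD and MaxAngle after
    optimal proper-rotation superposition. Ships an ideal A-form helix and
    junction generator so the full geometry pipeline can be exercised
    without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
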