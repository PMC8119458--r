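Package: rnarefine
Title: Knowledge-Based Orientation Potentials and Monte Carlo Refinement
    of RNA 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An orientation-dependent, knowledge-based statistical energy
    function for RNA nucleobases and backbone oxygen atoms, with
    quantum-chemistry-scaled reweighting of the base-base term, ribose
    rotamer and backbone torsion statistics, and an atomic clash term,
    coupled to a nucleobase-centric fold-tree Monte Carlo
    simulated-annealing sampler that refines near-native RNA 3D models.
    Includes statistics collection from a user-supplied corpus of PDB
    structures, a sphere codebook and orientation clustering under a
    pseudo-atom distance-matrix metric, and deterministic synthetic
    fixtures (ideal A-form helices, hairpin toys, decoys, planted-mode
    pair libraries) so the whole pipeline can be built and tested
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
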