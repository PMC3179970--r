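Package: rnpscore
Title: Knowledge-Based Statistical Potentials for Scoring Protein-RNA
    Docking Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Medium-resolution, coarse-grained statistical potentials for
    ranking rigid-body protein-RNA docking decoys.  Training complexes are
    reduced to united-atom beads (one to three per amino acid; phosphate,
    ribose and base-ring centroids per nucleotide), binned protein-RNA
    contact statistics are converted to energies by reverse Boltzmann
    inversion under either a quasi-chemical (mole-fraction) reference
    state or a decoys-as-reference-state (DARS) built from geometric
    docking decoys, and models are scored with a four-term function
    (distance, angle, nucleotide-edge and steric-clash terms).  Includes a
    rigid-body pose sampler for reference and test decoys, leave-one-out
    training, greedy RMSD clustering of best-scored decoys, and
    score-versus-RMSD evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
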