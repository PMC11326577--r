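Package: depolyscan
Title: Phage Depolymerase Detection by Per-Residue Fold Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects phage depolymerases from protein sequence. Every
    residue of a protein is labelled with one of four polysaccharide-
    degrading fold classes (none, right-handed beta-helix, n-bladed
    beta-propeller, triple helix) by a token classifier over a
    deterministic sequence-embedding backbone, and a stacked
    convolutional binary head turns the per-residue labels into a
    sequence-level depolymerase probability. Also provides the
    data-curation decision rules used to assemble fold-confirmed
    training sets (length filter, profile-search hit calling,
    cluster-representative selection, per-cluster annotation caps,
    structure-hit probability thresholds), domain delineation from
    per-residue labels or structural matches, group-shuffle data
    splitting, a synthetic labelled-sequence generator for desk-scale
    experiments, and a benchmarking suite (precision, recall,
    specificity, accuracy, F1, Matthews correlation coefficient,
    precision-recall AUC) with a false-positive reassessment
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
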