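Package: eciml
Title: Descriptor Ablation Analysis for Enzyme-Chemical Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much enzyme and chemical descriptors
    contribute to machine-learning predictions of enzyme-chemical activity
    relationships. Provides an activity-dataset container with FASTA/CSV/YAML
    readers and writers, dataset-characterization statistics (activity ratio,
    activity-order concordance indices, top-k Smith-Waterman and Tanimoto
    similarities), sequence-composition and chemical descriptors with shuffle
    and permutation information-ablation strategies, Random-Forest ablation
    variants with non-ML baselines, three cross-validation scenarios
    (new-relationship, new-enzyme, new-chemical) with the associated
    filtering rules and metrics (AUPR, AUROC, R2, MAE), post-hoc correlation
    and clustering analyses, and a synthetic dataset generator with ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    cluster,
    ranger,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
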