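Package: dmsimpute
Title: Imputation of Missing Deep Mutational Scanning Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing variant-effect scores in deep mutational scanning
    (DMS) experiments of protein domains. Scores are normalized to a scale
    anchored at wild type (1) and nonsense (0), per-variant feature vectors are
    assembled from substitution matrices, physicochemical amino-acid
    properties, a single-nucleotide-variant indicator, residue embeddings from
    a pluggable protein language-model provider, and a positional mean-score
    prior; a gradient-boosted tree regressor with group-aware hyperparameter
    tuning predicts scores for unmeasured substitutions. Includes
    nearest-neighbour and positional-mean baseline imputers, a full set of
    evaluation split schemes (random, leave-protein-out, leave-position-out,
    leave-variant-out, SNV-only, representative-substitution), an
    experimental-noise-ceiling estimator based on simulated assay replicates,
    dataset-completeness metrics, and a synthetic variant-effect-map generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
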