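Package: lipidsite
Title: Group-Based Prediction of Protein Lipid-Modification Sites
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trainable group-based prediction of four protein
    lipid-modification site types (S-palmitoylation, N-myristoylation,
    S-farnesylation, S-geranylgeranylation) from sequence alone.
    Candidate cysteines and glycines are scored against groups of known
    sites by position-weighted BLOSUM62 peptide similarity; groups come
    from recognition-motif classes or peptide k-means under a
    conserved-substitution distance, and the position weights and
    substitution scores are tuned by a particle swarm with an aging
    leader and challengers to maximize leave-one-out sensitivity at 90
    percent specificity.  Includes cross-validation and ROC/PR
    evaluation, stringency-threshold calibration, chi-square and
    hypergeometric statistics for dual-lipid co-regulation analysis, and
    a seeded synthetic-data generator with planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
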