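Package: vstriage
Title: Enrichment Statistics and Benchmark Evaluation for Virtual
    Screening Triage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluation machinery for benchmarks of binding-free-energy
    predictors used in virtual screening triage. Provides exact
    hypergeometric enrichment statistics for active/decoy score tables
    and a cumulative-probability-matching extrapolation of benchmark
    enrichment to realistic screening-campaign scale; accuracy metrics
    (Pearson, Spearman, RMSE, stratified splits, docking-pose
    sensitivity) for experimental versus calculated binding free
    energies; a lead-likeness curation funnel with amended Lipinski
    ranges, structural exclusion rules and SMARTS reactive-group
    alerts; Butina sphere-exclusion diversity clustering on circular
    fingerprints; per-complex structural descriptors (ligand burial,
    pocket lipophilicity, metal-site flagging) from PDB files; kernel
    density summaries of active/decoy score separation; and seeded
    synthetic-data generators so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
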