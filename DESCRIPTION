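Package: olfnet
Title: Olfactory Behavior, Connectome and Transcriptome Integration for
    Alzheimer's Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking olfactory-guided behavior, diffusion-MRI
    structural connectomes, Alzheimer's-disease risk traits and blood/brain
    transcriptomics in humanized APOE mouse cohorts. Provides behavioral
    indices (recognition, dishabituation, anhedonia, exploration AUC) with
    factorial Type III effect sizes; a two-stage Elastic Net plus multi-set
    canonical correlation (SUMCOR) integration of connectome edges, behavior
    and risk traits with bootstrap and permutation inference and subnetwork
    back-projection; transcriptomic eigengene construction and an
    eigengene-by-imaging-metric coupling grid with Benjamini-Hochberg FDR;
    brain-blood principal-component coupling with top-loading gene
    intersections and hypergeometric gene-set over-representation; and a
    synthetic-cohort generator with planted effects so every stage has a
    ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    car,
    emmeans,
    edgeR,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
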