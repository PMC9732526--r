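Package: ballistic
Title: Fusion Prioritization, Risk Signatures and Splicing Programs in B-ALL Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multicohort B-cell acute lymphoblastic
    leukemia (B-ALL) transcriptome analysis. Prioritizes gene fusions from
    caller output using evidence, artifact, recurrence and fusion allele
    frequency (FAF) filters; classifies and groups fusions by recurrent
    partner and mutual exclusivity; assesses protein-domain disruption at
    fusion breakpoints; builds a fusion-independent relapse-risk gene
    signature scored by a random-forest k-score with survival-based
    evaluation; quantifies percent-spliced-in (PSI) from transcript
    abundances and tests differential splicing with a logit-linear model;
    scans RNA-binding-protein motifs against GC/length-matched resampled
    controls; and tests event/risk co-occurrence with an exact probabilistic
    model. Ships a synthetic multicohort generator with a machine-readable
    truth ledger so every stage can be validated against planted signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    limma,
    survival,
    randomForest,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
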