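Package: driadce
Title: Cryptic-Exon Stratified Drug Repurposing Analysis for Alzheimer's Disease Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies Alzheimer's disease brain transcriptomes into
    TDP-43 pathology-positive and -negative groups using cryptic-exon
    transcript abundances (STMN2-short, UNC13A-CE1/CE2), predicts Braak
    disease stage from drug-derived gene sets with an L2-penalised
    cumulative-logit ordinal regression evaluated by age-matched
    leave-pair-out cross-validation, and assesses gene-set significance
    against size-matched random backgrounds with empirical p-values and
    Benjamini-Hochberg correction. Also provides a differential-expression
    stand-in with the -sign(LFC) x log10(p) ranking metric and a pre-ranked
    enrichment statistic for interferon-stimulated genes, a pooled CRISPR
    rescue-screen scorer (reads-per-million normalisation, log2 fold
    changes against a lipofectamine control, decimal round-half-up hit
    calling, hypergeometric gene-level p-values), and a synthetic-data
    generator emulating the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    glmnet,
    withr,
    jsonlite
Config/testthat/edition: 3
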