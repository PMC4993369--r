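Package: chromexpr
Title: Integrative Analysis of Histone Marks, Transcription and Histone PTM
    Stoichiometry in Compact Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating ChIP-seq histone-mark coverage with
    RNA-seq differential expression in gene-dense genomes. Provides coverage
    CPM normalization with sliding-window smoothing, strand-aware metagene
    profiling anchored at start or stop codons, per-gene mark quantification,
    TMM normalization with a moderated-t differential expression test,
    classification of genes into mark-by-expression groups, functional-category
    (secondary-metabolite cluster versus basic metabolism) enrichment via the
    hypergeometric test, heterochromatin (H3K9me3) domain calling with
    cluster-flanking analysis, and histone post-translational-modification
    stoichiometry from peptide-form relative abundances. A deterministic
    synthetic-data generator plants all of the structure the analysis assumes,
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
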