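Package: tethermoscan
Title: Transposable-Element Transcriptional Activity from De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transposable-element (TE) transcriptional activity in a
    de novo assembled transcriptome from RepeatMasker annotations and
    per-sample read counts, expressed as a percentage of mapped reads per TE
    class, type and element. Resolves redundant RepeatMasker hits by a
    best-score/length rule, calibrates gene expression across samples with a
    BUSCO single-copy-ortholog reference set, computes calibrated TPM for a
    silencing-gene panel, and tests condition effects by replicate one-way
    ANOVA with star annotation. Includes a negative-binomial synthetic-data
    generator with known ground truth for every pipeline stage, and a
    configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
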