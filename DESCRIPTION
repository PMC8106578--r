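Package: loyate
Title: Mosaic Loss of Chromosome Y Quantification and LOY-Associated
    Transcriptional Effects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mosaic loss of chromosome Y (LOY) in leukocytes from
    four data modalities: SNP-array log R ratios (median LRR over the
    male-specific region, batch correction, cell-fraction conversion),
    droplet digital PCR AMELY/AMELX counts with Poisson partitioning,
    bulk RNA-seq of sorted cell fractions via a variance-stabilizing
    transformation of chromosome-Y expression, and single-cell RNA-seq
    per-cell LOY calls from absent MSY transcripts. Detects LOY-Associated
    Transcriptional Effects (LATE) on autosomal and pseudo-autosomal genes
    with a negative-binomial GLM on binned LOY fractions, batch covariates,
    independent filtering and Benjamini-Hochberg FDR, plus an inter- versus
    intra-individual subtraction procedure for lymphoblastoid cell-line
    clones, a co-expression contrast, and disease-cohort comparisons. A
    synthetic-data generator with recorded ground truth backs every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
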