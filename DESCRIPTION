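Package: tr1kit
Title: Clonotype and Transcriptional Analysis of pMHCII-Nanomedicine-Induced
    Regulatory T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for antigen-specific CD4+ T cells
    expanded in vivo by peptide-MHC class II nanoparticles (pMHCII-NPs).
    Classifies single-cell TCR contigs into clonotypes by aligning them
    against a recombinome of all V-J germline combinations and grouping
    cells on identical V/junction/J identifiers; summarises repertoire
    structure (clonal sizes, V/J usage skewing with chi-square tests, CDR3
    length and positional residue enrichment, charged-residue motifs);
    quality-filters, clusters (PCA + k-means) and differentially analyses
    single-cell count matrices with a per-gene negative-binomial likelihood
    ratio test and a |FC| >= 4, FDR <= 0.01 significance rule; quantifies
    clonotype sharing between TFH-like and TR1-like expression clusters;
    and computes luciferase stimulation indexes for TCR reporter assays.
    Ships a synthetic-data generator that emulates the oligoclonal
    paired-chain repertoires and three-population expression structure of
    such experiments so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
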