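Package: methylscan
Title: Context-Resolved Methylome Analysis and Window-Based DMR Detection
    for Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-cytosine methylation call tables from
    whole-genome bisulfite sequencing in plants. Computes weighted
    methylation levels per CG/CHG/CHH context at site, bin and genome
    resolution; builds end-anchored average methylation profiles over genes
    and transposable elements; calls differentially methylated regions
    (DMRs) between two methylomes with a 50-nt window scan, gap-based
    merging, per-context difference thresholds and Fisher's exact test;
    annotates DMRs to promoters, gene bodies and transposable elements and
    summarises superfamily, family and cross-genotype overlap statistics;
    performs replicate-reproducibility PCA on shared CG sites; and
    simulates complete methylomes with compartment structure and planted
    DMRs of known coordinates and effect sizes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
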