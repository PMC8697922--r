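Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Layer RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA/circRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    regulatory networks from feature-by-sample count matrices of four RNA
    layers measured in two conditions, as in small two-group whole-transcriptome
    follicle studies. Provides the layer-specific abundance normalizations
    (FPKM, TPM, RPM, and RT-qPCR 2^-ddCt relative quantitation), a conditional
    negative-binomial exact test with trimmed-mean-of-M-values scaling factors
    and layer-specific differential-expression thresholds, the seven
    back-splice-junction filters used to call circRNA candidates, three-way
    miRNA target-prediction intersection gated by negative Spearman
    coexpression, Pearson-gated triplet admission into a typed ceRNA network
    with degree/hub analysis and GraphML/SIF export, hypergeometric term
    enrichment from GMT annotation, and a seeded synthetic multi-omic data
    generator with planted ground truth so the whole pipeline is testable
    without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
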