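Package: polypomics
Title: Multi-Omic Variant, Expression, Microbiome and Copy-Number Analysis for a Canine Polyposis Case Study
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computations behind a
    tumor/normal, WGS/RNA-seq multi-omic case study of canine extreme
    intestinal polyposis: a germline missense prioritization cascade with
    cross-assay concordance, uniqueness, annotation, read-support,
    polyp-selection and evolutionary-conservation steps; somatic consequence
    classification and the collapsed six-class substitution spectrum;
    FPKM computation, a per-sample outlier-expression statistic and
    single-sample gene set enrichment (ssGSEA) scoring with score-based
    sample clustering; host-depleted shotgun metagenomic profiling with
    rank-exclusive read-pair taxon assignment; and 1-kb tiling-window
    read-depth copy-number analysis with whole-chromosome gain calling.
    Every stage is exercisable on synthetic data with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ape,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
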