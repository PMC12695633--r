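Package: neoEscape
Title: Gland-Resolved Immuno-Editing and Immune-Escape Analysis for
    Multi-Region Colorectal Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how colorectal tumours evade immune predation using
    multi-region (gland-level) genomic, transcriptomic and chromatin
    accessibility data. Implements proportional neoantigen burden with
    clonal/subclonal accounting, genetic immune-escape calling (HLA mutations
    with second-tier rescue, HLA loss of heterozygosity, antigen-presenting
    gene disruption, checkpoint overexpression), promoter chromatin
    accessibility loss (SCAA) enrichment with permutation testing,
    a transcriptional immuno-editing classifier from RNA allele counts,
    opportunity-normalised immune dN/dS on immunopeptidome regions, and
    shared exact/mixed-model statistics. Ships a synthetic multi-gland cohort
    generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    lme4,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
biocViews: SomaticMutation, Epigenetics, ImmunoOncology, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
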