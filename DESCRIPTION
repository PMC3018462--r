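Package: SASpipe
Title: Cross-Platform Microarray Content Mapping and Sense-Antisense Pair
    Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares a generic genome-based microarray with a disease-specific
    transcriptome-based array at the probe level, and mines the
    disease-specific content for natural antisense transcripts. Implements
    exact probe-to-sequence matching with the six-probes-per-probeset rule to
    partition two platforms into common and unique content, MAS5 flag-call
    detection filtering and fold-change plus t-test differential expression
    cascades (replicated in-vitro and clinical majority-call variants),
    hypergeometric pathway over-representation, gene-level sense:antisense
    (SAS) pair discovery with cis-NAT overlap-category classification, and
    array-versus-qPCR fold-change concordance. Ships a synthetic transcriptome
    and platform generator with planted ground truth so that every stage of
    the pipeline can be exercised and validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Microarray, DifferentialExpression, GeneExpression, Annotation,
    Pathways, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SASpipe-package.R'
    'accessors.R'
    'concordance.R'
    'enrichment.R'
    'filters.R'
    'io.R'
    'mapping.R'
    'pipeline.R'
    'sas.R'
    'simulate.R'
    'utils.R'
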