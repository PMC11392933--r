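Package: mgatlas
Title: Cell-Type-Aware Annotation of GWAS Loci with Single-Cell Multiome Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates GWAS risk loci with barcode-shared single-nucleus
    ATAC and RNA (multiome) data. Implements candidate-causal-variant (CCV)
    selection from summary statistics by log-likelihood-ratio and linkage
    disequilibrium rules, a cell-type and category-specific candidate
    cis-regulatory element (cCRE) atlas with a quantile-based category
    assignment, CCV-cCRE colocalization, a per-cell trait relevance score
    with network propagation, allelic transcription-factor binding and
    Tn5-footprint scoring, a six-level cCRE-to-gene linkage classifier, and
    an additive 1-4 variant functional score. Ships a synthetic multiome
    generator with planted ground truth so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    irlba,
    RANN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: SingleCell, Epigenetics, GenomeWideAssociationStudy,
    FunctionalGenomics, GeneRegulation, ATACSeq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'io.R'
    'atlas.R'
    'ccv.R'
    'linkage.R'
    'scoring.R'
    'trs.R'
    'tf.R'
    'synthetic.R'
    'pipeline.R'
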