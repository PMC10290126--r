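Package: calciproteo
Title: Proteogenomic Identification of Coccolithogenesis Candidate Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate calcification
    (coccolithogenesis) proteins in the coccolithophore Emiliania huxleyi
    from proteomic and comparative-genomic evidence. Provides
    phylostratigraphic origin assignment of orthogroups on a guide tree
    with lineage-specific loss detection and hypergeometric domain
    enrichment; search-database completeness metrics based on de novo
    score gating and greedy spectral clustering; sequence-property
    scanners (SEG-style low-complexity segmentation, disorder propensity,
    compositional bias, motif over-representation, Ser-Pro repeats);
    empirical-Bayes moderated t-tests for TMT reporter intensities; the
    rule-based candidate filters defining coccolith-occluded (COPRO),
    coccosphere and coccolith-vesicle protein sets; and cross-dataset
    overlap prioritization. Includes seeded synthetic-data generators
    with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'calciproteo-package.R'
    'candidates.R'
    'diffabund.R'
    'formats_io.R'
    'phylostrat.R'
    'pipeline.R'
    'seqfeat.R'
    'spectral_qc.R'
    'synthetic.R'
    'tree-utils.R'
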