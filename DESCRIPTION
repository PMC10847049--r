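Package: viroflow
Title: Gut Virome Contig Triage, Spike-In Quantification and
    Restoration Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for faecal virome metagenomics in
    intervention studies: multi-evidence triage of assembled contigs into
    putative viral sequences (nucleotide homology coverage, protein-hit
    density, stand-alone classifier calls, circularity), redundancy
    removal, provirus refinement and quality-based quantitative
    inclusion; breadth-of-coverage filtering of mapping counts with
    length/total-sum normalisation and spike-in anchored absolute
    abundance; compositional (centred log-ratio) community statistics
    including Aitchison beta-diversity, PERMANOVA and Hill-number alpha
    diversity; per-feature stress-alteration/restoration testing by
    orthogonal contrasts with Tukey post hocs, Benjamini-Hochberg FDR
    and a longitudinal random-intercept variant; phage-bacteria
    correlation networks annotated against host predictions; and seeded
    synthetic-data generators with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    emmeans,
    optparse,
    withr
Config/testthat/edition: 3
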