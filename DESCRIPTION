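Package: trnamod
Title: Quantification of Substoichiometric tRNA and tsRNA Modifications
    from Modification-Mapping Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify substoichiometric tRNA and tRNA-fragment
    (tsRNA) modification levels from three modification-mapping sequencing
    chemistries: RiboMethSeq for 2'-O-methylation (Nm), RNA bisulfite
    sequencing for m5C, and AlkAnilineSeq for m7G, m3C and dihydrouridine.
    The package builds a reduced consensus "tRNA genome" with Sprinzl
    position numbering, converts read alignments or count tables into
    per-position signals, computes the chemistry-specific scores (RiboMethSeq
    Scores A, B, C/MethScore and Mean, AlkAnilineSeq stop ratio, bisulfite
    non-conversion rate), calibrates noise thresholds, curates candidate
    sites against modification-type plausibility rules, classifies site
    variability, and extracts principal-component signatures that separate
    RNA species, cell lines and treatments. A synthetic-data module
    generates count tables with known ground-truth stoichiometries so the
    whole workflow can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    cluster,
    dplyr,
    ggplot2,
    pheatmap,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
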