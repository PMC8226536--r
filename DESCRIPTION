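Package: pseudoquant
Title: Pseudogene-Aware PCR Assay Design and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for measuring true transcription of genes shadowed by
    processed pseudogenes. Discovers intronless, highly homologous copies of a
    target cDNA in a genome and classifies them as parent, pseudogene, or
    diverged paralog; designs allele-specific, splice-junction, and
    primary-transcript (intron-targeted) PCR assays that discriminate the
    parent gene from its pseudogenes; predicts cross-amplification in silico
    with a 3'-weighted mismatch model; and provides the quantification stack:
    threshold-based CT calling, delta-delta-CT fold change, standard-curve
    amplification efficiency, digital-PCR Poisson quantification and pool
    fractions, mitochondrial DNA copy number, JC-1 membrane-potential fold
    change, poly-T amplicon sizing, and bootstrap neighbor-joining phylogeny
    of the paralog family. Includes seeded synthetic-data generators that
    emulate the full study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
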