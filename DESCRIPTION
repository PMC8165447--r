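Package: famscan
Title: Gene Family Identification, Molecular Evolution and Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparative analysis of plant
    transcription-factor gene families across related genomes: conserved-domain
    scanning with Karlin-Altschul E-values, subfamily classification from
    diagnostic domain features, progressive multiple alignment and
    neighbor-joining phylogeny, tandem versus segmental duplication typing,
    Nei-Gojobori (1986) Ka/Ks estimation with sliding-window selection maps,
    strand-aware promoter extraction with IUPAC cis-element census, and
    2^-ddCt relative expression from replicated qPCR Ct tables. Ships a
    synthetic-genome simulator that plants gene families, duplicate pairs
    diverged under a known omega, promoter motifs and Ct tables with
    machine-readable truth, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
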