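Package: mitocomp
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of circular fungal
    mitochondrial genomes: GenBank/FASTA input and output for annotated
    circular genomes, base composition and AT/GC strand-skew statistics,
    genome region partitioning with size-expansion contribution rates,
    codon usage under the mold mitochondrial genetic code (table 4),
    Kimura two-parameter distances and Nei-Gojobori (NG86) Ka/Ks
    estimation for core protein-coding genes, interspersed and tandem
    repeat detection, group-I intron position-class (Pcl) homology
    against a reference coding sequence, circular gene-order breakpoint
    and positional-change analysis, concatenated supermatrix
    construction with neighbor-joining trees, and a synthetic mitogenome
    generator with recorded ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
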