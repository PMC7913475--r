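Package: cystakit
Title: Motif-Grammar Annotation, Classification and Gain-Loss Evolution of
    Cystatin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural-bioinformatic survey of cysteine protease
    inhibitors (cystatin superfamily) in early-emerging metazoan lineages.
    Provides a six-frame translated local-alignment homology screen with
    iterative query expansion, grammar-based detection of the conserved
    cystatin-domain motifs (amino-terminal trunk glycine, Q-x-V-x-G first
    hairpin loop, the LP/PW second-hairpin pair, the D-x-L-x-Y-F stefin
    carboxy terminus and two flanking conserved residues), rule-based
    classification into classical stefins, atypical stefins (type 1/2) and
    type 2 cystatins, intron mapping from genomic/cDNA comparison with GT/AG
    junction handling, alignment trimming and sequence-logo information
    content, p-distance neighbor-joining utilities, Fitch and Dollo parsimony
    with enumeration of alternative gain-loss scenarios on a species tree,
    and a ground-truth synthetic gene-family generator that exercises every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
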