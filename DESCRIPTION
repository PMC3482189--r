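Package: strucphylo
Title: Phylogenetics on rRNA Secondary-Structure Recoded Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recodes ribosomal RNA alignments into a 20-symbol
    secondary-structure alphabet (4 unpaired-base symbols plus 16
    ordered base-pair doublet symbols), infers phylogenies over that
    alphabet by maximum likelihood (Felsenstein pruning over generic
    k-state substitution models with discrete-gamma rate variation)
    and maximum parsimony (Fitch scoring with NNI search), attaches
    nonparametric bootstrap support, and reconstructs ancestral states
    of discrete morphological characters on support-collapsed trees
    under the Mk model and parsimony.  Includes a seeded simulator for
    stem/loop structured alignments and the fixtures needed to rerun
    the analysis workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
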