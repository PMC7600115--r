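Package: tadir
Title: TAD Calling, Differential Interaction Testing, and Promoter
    Coherence Analysis for Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chromatin reorganization between two
    cellular conditions from Hi-C valid-pairs data: read-pair
    classification, contact-matrix binning and iterative correction (ICE),
    directionality-index TAD calling with a Gaussian hidden Markov model,
    negative-binomial quasi-likelihood testing of differential chromatin
    interactions at bin-pair resolution with loess MA-plot offsets and
    Benjamini-Hochberg control, and promoter-promoter interactome
    coherence classification against gene expression. A synthetic Hi-C
    generator with planted domains, differential bin pairs, and coherent
    expression groups supports end-to-end validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
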