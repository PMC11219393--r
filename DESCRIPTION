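Package: bitterfam
Title: Birth-and-Death Analysis of Bitter Taste Receptor Gene Repertoires
    from Targeted-Capture Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes TAS2R bitter-taste-receptor gene repertoires from
    targeted-capture style summary data. Provides depth and SNP-density based
    paralog and absence calling with median-inclusive boxplot outlier fences,
    open-reading-frame and seven-transmembrane classification of gene
    sequences into intact, disrupted and segregating-pseudogene states,
    Tamura-Nei neighbor-joining gene trees with bootstrap support, and
    Dollo-style maximum-parsimony placement of gene birth and death events on
    a dated species tree under a gene-conversion assumption. A forward
    simulator of diploid gene-family histories and capture-style depth/SNP
    emissions makes every stage testable without external data, and a
    packaged cercopithecid example reproduces the headline event counts of a
    capture study of ten Old World monkey species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
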