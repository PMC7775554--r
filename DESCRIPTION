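Package: fracsig
Title: Mechanism Signatures of Duplicate-Gene Loss in Synteny Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes DNA excision from pseudogenization as the mechanism
    of duplicate-gene loss after whole-genome duplication or speciation.
    Chains homologous gene pairs into collinear synteny blocks, scans retained
    blocks for deletion intervals where one homeologous region has lost a run
    of genes, measures the residual DNA on the fractionated side against the
    conserved DNA on the unfractionated side, and compares the two
    base-pairs-versus-interval-length regressions (excision leaves a flat,
    near-zero residual; pseudogenization leaves DNA that grows with the number
    of missing genes). Includes a translocation audit for block singletons and
    a forward simulator of genome pairs with a ground-truth event log.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
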