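Package: mirnet
Title: Integrated miRNA:mRNA Time-Course Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers phase-resolved microRNA regulatory networks from paired
    mRNA microarray and miRNA qPCR time courses, as used to study growth
    factor induced differentiation (e.g. FGF2-treated lens epithelial
    explants profiled at 0, 2, 4, 12 and 24 hours). Provides ANOVA and
    fold-change differential-expression filtering, temporal template
    matching into early/late up/down classes, canonical seed-site target
    prediction on 3'-UTRs (6mer, 7mer-A1, 7mer-m8, 8mer), phase-wise
    inverse miRNA:mRNA pairing, connectivity-ranked bipartite network
    extraction with hub and genomic-cluster detection, hypergeometric
    over-representation analysis, and a synthetic time-course generator
    with planted regulatory structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    igraph,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
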