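Package: mosaicscan
Title: Sliding-Window Phylogenetic Incongruence Scanning and Peptide
    Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mosaic gene loci shaped by horizontal transfer by
    scanning a nucleotide alignment with a moving window, building a
    neighbor-joining tree per window from Jukes-Cantor distances, and
    comparing window trees with a branch-length-aware K tree score.
    Windows incongruent with a reference species tree are segmented into
    contiguous regions with breakpoint estimates, and strains are
    clustered into alleles within the incongruent region. Also provides
    an erf-based dose-response model for peptide import (half-maximal
    concentration and plateau estimation by multi-start nonlinear least
    squares), geometric-mean fold-change statistics with logarithmic
    standard errors for sporulation efficiencies, and simulators that
    generate all of these data types with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    pracma
Config/testthat/edition: 3
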