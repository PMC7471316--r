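Package: umisat
Title: UMI Saturation and De-Duplication Distortion in Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the complexity of unique molecular
    identifiers (UMIs) limits de-duplication accuracy in small RNA
    sequencing. Provides a synthetic small-RNA library generator with
    skewed miRNA abundances, isomiR variants, flanking 4-nt UMIs,
    PCR amplification bias and sequencing error; a deterministic
    adapter/UMI read parser; Hamming-distance UMI de-duplication
    (unique, cluster and directional methods); isomiR- and miRNA-level
    quantification with counts-per-million and fold-underestimation
    reporting; and closed-form birthday/occupancy collision mathematics
    with a matching Monte-Carlo saturation simulation used to choose an
    adequate UMI length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
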