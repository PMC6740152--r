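Package: sidekit
Title: Discovery and Annotation of Short Internally Deleted Elements and
    Their Partner LINE Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for short internally deleted elements
    (SIDEs), nonautonomous retroelements formed by internal deletion of a
    non-LTR (LINE) retrotransposon such as CR1. Provides a seed-and-extend
    local-alignment genome scanner with Karlin-Altschul e-values, iterative
    majority-rule consensus reconstruction, structural annotation of
    SIDE/LINE architecture (homologous 5'/3' blocks, poly-A tails,
    target-site duplications, breakpoint microhomologies, sequence logos),
    fragment filtering and defragmentation, Jukes-Cantor divergence
    landscapes ("activity through age"), cross-genome copy-number
    correlation, and a ground-truth synthetic genome generator for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
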