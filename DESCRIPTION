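Package: raresight
Title: Design and Interpretation of Rare-Variant Sequencing Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation machinery for planning and interpreting
    rare-variant case-control sequencing studies. Computes burden-test power
    through a non-centrality parameter driven by the ascertained minor
    allele frequency spectrum, the marginal disease risk carried by novel rare
    variants whose effects are random, per-variant discovery (ascertainment)
    probabilities in finite case-control samples, a Monte-Carlo simulator of
    the winner's curse affecting pooled rare-variant effect estimates, and the
    per-variant effect sizes implied by common burden-test weighting schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
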