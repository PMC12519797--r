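Package: breakrank
Title: Ranking De Novo Assembly Candidates by DNA Breakage Propensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proof-of-concept toolkit showing that prior octamer (8-mer)
    DNA breakage probabilities can rank candidate de novo assembly
    solutions. Simulates sequence-context-biased fragmentation (as in
    ultrasonication library preparation) of known references, emits
    fixed-length ultrashort reads, assembles them with a small de Bruijn
    graph assembler, scores every candidate scaffold with a breakage
    propensity score (BPS, the probability-weighted sum of inferred
    breakpoint octamers), and validates that higher BPS tracks lower
    Levenshtein distance to the ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
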