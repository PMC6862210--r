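Package: srnec
Title: Alignment-Free Enzyme Classification with Sequence Recurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms protein sequences into sequence recurrence networks
    (SRNs), derives Markov-matrix trace and Markov-Shannon entropy descriptors,
    assembles multi-task feature tables pairing each sequence with candidate
    Enzyme Commission (EC) subclasses via class means and deviations, and
    classifies sequences as enzyme-of-subclass versus not with a published
    linear discriminant equation or retrained linear and neural classifiers.
    Includes confusion-matrix statistics (per-class rates, accuracy, Matthews
    correlation), single-discriminant identities (Wilks' lambda, canonical
    correlation), and a seeded synthetic-data generator with class-structured
    residue composition for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    nnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
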