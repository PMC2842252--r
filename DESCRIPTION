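Package: plmscan
Title: Discovery of Preferentially Located Motifs in TSS-Aligned Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab-initio discovery of preferentially located motifs (PLMs) in
    promoter sets aligned on the transcription start site. Positional motif
    distributions are scored against a sliding-window background model fitted
    by linear regression over an upstream learning region, peaks are ranked by
    the score of maximal square (SMS), and motif classes (canonical TATA-box,
    TATA variants, dinucleotides, TC-elements) are discovered by an iterative
    promoter-subtraction cascade across two species. Includes single-substitution
    motif distance graphs with seed identification, greedy one-base motif
    extension under an SMS-improvement rule, PLM-to-initiator spacing profiles,
    expression-breadth classification against a cubic baseline, orthologue
    conservation statistics, and synthetic promoter generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
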