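Package: hpknot
Title: Prediction of RNA H-Type Pseudoknots with Bulges and Internal Loops
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts H-type pseudoknots in RNA sequences by exhaustive
    enumeration of crossing core-stem quadruples, contiguous stem extension,
    and bulge/internal-loop gap-mediated extension bounded by a maximum bulge
    size, followed by a two-stage selection that maximises base pairing around
    the pseudoknot and then minimises a free-energy score combining a
    pseudoknot penalty with Turner-style nearest-neighbor stacking terms.
    Includes extended dot-bracket I/O with two bracket layers, per-position
    confusion-matrix evaluation (PPV, recall, F1, MCC) with slip-tolerant
    core-stem matching, a seeded generator of sequences with planted
    pseudoknots for benchmarking, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
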