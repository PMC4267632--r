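Package: costruct
Title: Simultaneous Folding and Alignment of Two Homologous RNAs with
    Inserted Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the common pseudoknot-free secondary structure and
    the structural alignment of two unaligned homologous RNA sequences by
    minimizing a joint nearest-neighbor free energy.  Beyond the classic
    Sankoff-style simultaneous fold-and-align, the recursions explicitly
    allow folding domains inserted in one homolog (with affine
    opening/elongation penalties), stem extensions, and internal loops
    aligned to stacked base pairs.  Includes a banded dynamic-programming
    core, single-sequence folding with the auxiliary arrays required by the
    insertion recursions, brute-force enumeration oracles for validation,
    synthetic homolog-pair fixtures, CT/dot-bracket/FASTA/alignment I/O,
    and slip-tolerant sensitivity/PPV evaluation with paired significance
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
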