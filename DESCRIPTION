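Package: banddp
Title: Banded Dynamic Programming Alignment for Long Error-Prone Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise global and semi-global (overlap) alignment of long,
    error-prone nucleotide reads by dynamic programming restricted to a
    diagonal band. The band half-width is chosen from a random-walk model of
    insertion/deletion accumulation (w = k * sigma_d with
    sigma_d = sqrt(2 N p)), widened in stages when needed, and the banded
    score is certified as optimal via a score bound for global alignments
    and a two-criteria procedure (band-edge contact and match-count
    confidence bound) for semi-global alignments. Includes a per-base
    substitution/indel read simulator with ground-truth event logs and
    simulation harnesses that validate the band model at configurable
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
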