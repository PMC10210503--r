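Package: pirnaconv
Title: Small RNA Analytics for piRNA Cluster Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the conversion of naive sequences into
    piRNA-producing loci from ovarian small RNA sequencing data mapped to
    user-supplied reference regions. Provides 3' adapter trimming,
    ungapped mismatch-tolerant read mapping with exhaustively defined
    semantics, small RNA library annotation and per-million normalization,
    piRNA and siRNA metrics (size distributions, 1U bias, ping-pong
    overlap z-scores, strand-resolved coverage and densities per kb),
    transgenerational conversion kinetics, RT-qPCR and ChIP-qPCR
    normalization statistics, egg-chamber repression summaries, and a
    fully seeded synthetic-data generator that emulates the statistical
    structure of germline small RNA libraries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
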