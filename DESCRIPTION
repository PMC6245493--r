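Package: stagealign
Title: Staged Exact Pairwise Alignment of Long DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact pairwise alignment of long DNA sequences with a staged,
    column-partitioned pipeline. Provides quadratic-space reference kernels
    (Needleman-Wunsch global, Smith-Waterman local, Gotoh affine-gap),
    Hirschberg/Myers-Miller linear-space traceback, wavefront (anti-diagonal)
    band computation with border-column exchange and special-row
    checkpointing, and a multi-worker staged traceback with pipelined or
    speculative crosspoint resolution. Includes alignment characterization
    statistics (matches, mismatches, gaps, coverage), cell-update performance
    and energy-cost accounting, a synthetic homologous-pair generator for
    desk-scale testing, FASTA input and gapped-FASTA/TSV output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
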