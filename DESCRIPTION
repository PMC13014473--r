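Package: squigseg
Title: Signal-to-Sequence Segmentation of Nanopore Current Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns basecalled nucleotide sequences to their raw nanopore
    current traces ("squiggles") with a two-state align/extend hidden Markov
    model, computing full forward-backward matrices in log space and
    extracting a maximum a posteriori segmentation with per-segment posterior
    confidence. Includes k-mer pore model I/O, signal normalization, banded
    dynamic programming, Baum-Welch retraining of transition and emission
    parameters, a synthetic squiggle simulator with ground-truth segment
    labels, and a segmentation benchmarking suite (border contrast, segment
    homogeneity, read statistics, normalized 0-1 scores and aggregated metric
    scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
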