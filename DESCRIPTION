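Package: quanvseq
Title: Quantum-Classical Hybrid Convolutional Models for Base-Resolution
    Transcription Factor Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a quanvolutional (quantum convolutional) first layer
    for base-resolution transcription factor binding site prediction from DNA
    sequence. Small parameterized quantum circuits are simulated exactly as
    statevectors and embedded, via a kernel-division strategy, into a
    U-net-like fully convolutional encoder-decoder that predicts per-base
    binding probabilities or continuous ChIP-seq binding signal. Includes
    ENCODE-style dataset construction from FASTA/BED/bedGraph inputs, a
    planted-motif ChIP-seq simulator with ground truth, training with hard
    negative mining or RMSE losses, base-resolution evaluation metrics,
    filter-activation motif extraction with information content, an internal
    PWM scanner with exact p-values, and motif co-occurrence distance
    analytics for cooperative binding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
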