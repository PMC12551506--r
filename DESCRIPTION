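Package: quantalign
Title: Simulated INT8 Quantization for Embedding-Based Biomedical Ontology Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying post-training INT8 (W8A8) quantization of text
    encoders used in embedding-based ontology alignment. Provides simulated
    integer quantization arithmetic with per-tensor and per-channel scales and
    smoothing-factor redistribution of activation outliers to weights, a
    deterministic positionwise text encoder with interchangeable FP32 and
    quantized execution paths, batched cosine-similarity alignment between a
    layman lexicon and an ontology string table in the pipe-delimited RRF
    dialect, rated-alignment complementarity merging, constraint-filtered
    Pareto search over quantization configurations, and an evaluation suite
    (EDRM, triplet mean average precision, Spearman correlation). A seeded
    synthetic-corpus generator supplies aligned lexicon/ontology fixtures with
    known ground truth so the whole pipeline is testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
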