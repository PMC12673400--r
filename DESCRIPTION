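Package: pepfunnel
Title: Generative Peptide Design with a Recurrent Next-Residue Model and a
    Biophysical Screening Funnel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de novo design of short functional peptides by
    autoregressive sequence modelling. Trains a bidirectional long short-term
    memory (BiLSTM) next-residue model in two phases (a base corpus of
    full-length proteins, then fine-tuning on short peptide chains), generates
    candidate peptides by seeded greedy decoding, and reduces the pool through
    a two-stage physicochemical funnel (Shannon entropy, GRAVY hydropathy,
    Guruprasad instability index, and Euclidean distance to the fine-tuning
    reference centroid) followed by global-alignment percent-identity
    prioritisation against the fine-tuning references. Includes synthetic
    corpus generators with planted, exactly recoverable structure so the whole
    pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
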