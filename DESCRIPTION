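Package: admetfusion
Title: Multi-Task ADMET Prediction with SMILES Transformers and Feature-Fusion Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for multi-label prediction of ADMET (absorption,
    distribution, metabolism, excretion, toxicity) endpoints from drug-like
    molecules. Implements a byte-pair-encoding tokenizer for SMILES strings,
    a small transformer encoder pre-trainable with a masked-language-model
    objective, and six fusion architectures (DNN, encoder, concat, pipe and
    two self-attention variants) that combine physicochemical descriptors
    with learned sequence representations. Includes the full training
    protocol (7:1.5:1.5 splits, AdamW, early stopping, multi-seed
    replication), per-label evaluation metrics, six-model ensemble voting
    with tie-breaking, and abundance-weighted aggregation of cytochrome
    P450 substrate calls. A synthetic molecule generator with planted,
    controllable structure- or feature-driven label signal makes every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
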