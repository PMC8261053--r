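Package: bendr
Title: Self-Supervised Contrastive Pre-Training of Transformer
    Representations for Raw EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes heterogeneous multichannel EEG recordings into a
    canonical 20-channel, 256 Hz representation, encodes them with a
    strided one-dimensional convolutional stack into BENDR feature
    sequences, and pre-trains a transformer contextualizer with a masked
    contrastive (InfoNCE-style) objective. Six transfer-learning
    configurations fine-tune the pre-trained stages on downstream
    classification tasks with leave-subject-out evaluation, balanced
    undersampling, and bootstrap confidence intervals. Includes a
    synthetic EEG generator with controllable oscillatory structure and
    class effects so the full pipeline is testable at desk scale, plus
    minimal EDF read/write support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pROC,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
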