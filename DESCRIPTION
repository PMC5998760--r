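Package: adrtag
Title: Semi-Supervised Bi-LSTM Extraction of Adverse Drug Reaction Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts adverse drug reaction (ADR) mentions from short, noisy
    social-media text by sequence labeling with a bidirectional LSTM. The
    encoder is first pretrained on an unsupervised drug-name-prediction task
    (drug mentions are located with a lexicon, masked with a dummy token, and
    the network predicts the masked drug from its context), then fine-tuned as
    a per-token IO tagger on a small annotated corpus. Includes tweet-style
    text normalization, lexicon matching, IO tag encoding, approximate
    span-match evaluation, a seeded synthetic-corpus generator for end-to-end
    benchmarking without access to restricted social-media data, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
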