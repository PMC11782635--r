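Package: fedlhe
Title: Federated Learning with Homomorphically Encrypted Aggregation for
    Two-Class Pathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation of privacy-preserving federated learning
    for benign/malignant classification of histopathology-like images.
    Implements sample-size-weighted federated averaging in which client
    model updates are quantized to a fixed-point integer code, packed into
    polynomial coefficient slots, and encrypted under an additively
    homomorphic scheme built on an RSA-style two-prime key generation, so
    the server aggregates ciphertexts without seeing any client's weights.
    Includes a 4-round XOR/XNOR/swap block transform for request payloads,
    a small residual convolutional surrogate classifier with magnitude-based
    hidden-layer pruning and transfer fine-tuning, a synthetic two-class
    image generator with magnification tags, YOLO-format annotations and
    non-IID client sharding, and a command-line pipeline for end-to-end
    experiments. The cryptography is a faithful re-implementation of a
    described construction for research use, not production-strength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
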