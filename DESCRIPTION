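Package: parzenfp
Title: Compressed Parzen Window Classification of Binary Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kernel density estimation and Bayes classification on binary
    feature vectors such as molecular fingerprints, using the
    Aitchison-Aitken discrete kernel. Provides the brute-force Parzen
    Window class-conditional estimator, a truncated power-series variant,
    and a compressed estimator whose per-class model is one scalar, two
    length-L vectors and one sparse L-by-L matrix -- its size independent
    of the number of training prototypes. Includes readers and writers for
    bit-string and hex-encoded fingerprint files, versioned model
    persistence, a synthetic fingerprint generator for benchmarking, and a
    command-line interface for fitting, prediction and backend comparison.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
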