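Package: cipherDDP
Title: Privacy-Preserving Outsourced Solving of the Double Digest Problem
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing restriction-site physical maps from
    double digest experiments without disclosing the measured fragment
    lengths. Fragment-length multisets are encrypted with an
    order-preserving homomorphic index scheme (a symmetric, probabilistic,
    decryption-free encoding that supports addition, subtraction and order
    comparison on ciphertexts); a quantum-inspired genetic algorithm then
    searches permutation pairs that solve the double digest problem
    directly over the ciphertexts, so that an untrusted compute server
    only ever sees encrypted lengths and returns plaintext-free mapping
    sequences. Includes the plaintext double digest model and a
    brute-force oracle, a synthetic cut-site instance generator,
    success-rate experiment runners, and executable forms of the scheme's
    security arguments (one-wayness bounds, lazy-server acceptance
    probability, and quantile-quantile ciphertext distribution checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
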