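Package: vulnscreen
Title: Dual High-Throughput Screen Analysis for Genetic Vulnerability Discovery
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deconvolution of paired RNAi and small-molecule viability screens
    used to nominate cancer vulnerability genes. Implements plate normalization
    and robust Z-scoring of siRNA screens, common-seed (CSA) off-target
    correction, heavy-tailed (exponential-power) activity modelling with
    tail-based significance cutoffs, redundant siRNA activity (RSA)
    hypergeometric gene ranking, Haystack seed-complementarity regression,
    verification-screen scoring and expression filtering, plus a quantitative
    HTS dose-response arm: control-based viability normalization, grid-based
    outlier-tolerant four-parameter logistic fitting, normalized AUC, absolute
    IC50 and relative EC50, and genotype-class summaries. A synthetic-data
    module simulates screens with recorded ground truth so every stage can be
    verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
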