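Package: exoref
Title: Unbiased Reference-Gene Discovery for Exosome Expression Data
Version: 0.1.0
Authors@R:
    person("exoref", "developers", email = "exoref@example.org", role = c("aut", "cre"))
Description: Discovers candidate reference (housekeeping) genes and miRNAs for
    qRT-PCR normalization of serum-exosome cargo from RNA-Seq/miRNA-Seq count
    matrices. Implements TPM/CPM/Ct normalization, a negative-binomial
    non-differential-expression screen of each cancer subtype against healthy
    controls, pooled high-expression filtering, stability scoring by the
    coefficient of variation and the geNorm average expression stability M,
    NormFinder-style group-aware validation scores, geometric-mean stability of
    multi-gene combinations, and CV+M rank-sum candidate ranking. Ships a
    negative-binomial simulator with planted stable features so the whole
    pipeline is testable without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    matrixStats,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
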