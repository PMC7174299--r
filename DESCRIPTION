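Package: polyshift
Title: Within-Generation Polygenic Selection from Pool-Seq Allele Frequency Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect polygenic selection within a single generation
    from pooled whole-genome sequencing data. Implements an absolute allele
    frequency difference (AFD) genome scan over per-site nucleotide count
    tables with chromosome-specific tail thresholds and candidate-region
    clustering, a reference-versus-survivor allele frequency shift test with
    an exact binomial sign test and a matched-MAF neutral resampling null
    (including the published robustness variants), individual-based forward
    simulators of single- and multi-generation polygenic viability selection
    under multiplicative and additive (zero-truncated) multilocus fitness,
    and a synthetic-data generator that emulates the pooled sequencing design
    of a lake-stream stickleback release-recapture experiment so every stage
    can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
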