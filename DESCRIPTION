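Package: azfcnahr
Title: AZFc Amplicon Copy Number, NAHR Scenario Reconstruction and Y-STR Dating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Read-depth analysis of the human Y-chromosome AZFc region:
    amplicon copy-number calling from per-base sequencing depth normalized by a
    1-Mb single-copy region, exponential-moving-average depth profiling against
    control samples, exhaustive reconstruction of non-allelic homologous
    recombination (NAHR) duplication/deletion scenarios explaining an observed
    copy-number vector (with gene-family dosage and Y-STR copy consequences),
    and ASD-based coalescence dating of Y-STR haplotype clusters under the
    stepwise mutation model. Includes synthetic-data generators so every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
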