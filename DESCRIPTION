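Package: mmrscreen
Title: Analysis of an Oligonucleotide-Directed Mutagenesis Screen for
    Mismatch-Repair Variant Classification
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse a cell-based functional assay that classifies
    MSH6 missense variants of uncertain significance by their effect on DNA
    mismatch repair (MMR). Covers genotype classification of 6-thioguanine
    resistant colonies (loss-of-heterozygosity exclusion, background
    filtering, sequence confirmation), the two-independent-colony
    pathogenicity call, zero-failure sensitivity/specificity bounds,
    Luria-Delbrueck slippage-rate estimation from (G)10-neo fluctuation
    assays, MNNG-induced mutagenesis frequencies, Welch one-tailed
    comparisons, and a seeded stochastic simulator of the whole screen so
    every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
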