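Package: seedtox
Title: Seed-Based Toxicity Analysis of RNAi Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing death induced by survival gene elimination
    (DISE), the sequence-specific toxicity of si/shRNAs that silence networks
    of survival genes through miRNA-like seed matches in 3'UTRs. Derives guide
    strands and 6mer/8mer seeds from printed si/shRNA sequences, enumerates
    single-nucleotide-tiled shRNA libraries with their 143-nt cloning inserts,
    quantifies pooled-screen depletion (subpool percentage normalization and
    cross-replicate fold-downregulation formulas), computes the seed-match
    Toxicity Index over survival versus nonsurvival gene sets, and provides
    the accompanying statistics: one-sided Mann-Whitney rank enrichment, a
    permutation Mann-Whitney test of TI association, Fisher's exact
    seed-by-downregulation test, binomial enrichment, GC correlations, and a
    sliding hypergeometric seed-enrichment landscape. Includes synthetic-data
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
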