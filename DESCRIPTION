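Package: phasekin
Title: Methylation Kinetics Analysis of Nucleosome Phasing and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromatin accessibility in living cells from DNA
    methyltransferase induction time courses. Converts DpnI-style fragment
    ends into per-GATC-site methylated fractions, estimates per-site apparent
    first-order methylation rate constants, normalizes them to a
    non-nucleosomal internal control (mitochondrial DNA median or genome
    median), fits a decaying sine wave model to nucleosome phasing profiles
    aligned on +1 nucleosome dyads, derives per-gene bias-corrected mean
    rates with quintile grouping, and dissects TFIIIB/TFIIIC transcription
    factor footprint dynamics at tRNA genes. Includes a synthetic-data
    generator producing toy genomes with known phased rate landscapes so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
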