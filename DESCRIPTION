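Package: palaeovar
Title: Simulation of Post-Mortem DNA Damage and Its Impact on Short-Read
    Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-seeding simulation pipeline for quantifying how ancient-DNA
    damage affects variant discovery from short reads. Simulates reference and
    divergent diploid sample genomes under an HKY substitution model with
    discrete-gamma rate heterogeneity, invariant sites and power-law indels;
    synthesizes single-end read pools trimmed to fragment-size distributions
    typical of degraded DNA; layers on post-mortem damage (fragmentation bias
    at fragment ends and terminal cytosine-deamination misincorporations with
    exponential positional decay); maps reads back to the reference with a
    built-in seed-and-extend aligner; calls diploid SNPs and indels from
    pileups; profiles realized damage from the mapped reads; and scores calls
    against the recorded truth (accuracy, completeness, homozygote:heterozygote
    recovery) across a factorial grid of GC content, divergence, read length,
    damage level and coverage depth, with regression summaries of each
    factor's effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    vcfR
Config/testthat/edition: 3
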