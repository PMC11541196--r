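Package: adpopgen
Title: Population-Genetic Analysis of Ancient DNA Time Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for allele-frequency based population genetics of
    low-coverage ancient DNA. Reads EIGENSTRAT genotype data, performs
    damage-aware pseudohaploid genotype calling, genetic sex typing from
    X/Y coverage, pairwise mismatch rates and conditional nucleotide
    diversity. Computes f2, f3, f4 and FST statistics with weighted block
    jackknife standard errors, rank (clade/continuity) tests and
    admixture-proportion estimation on systems of f4 statistics with
    model selection, X-versus-autosome sex-biased admixture inference,
    and admixture dating from the exponential decay of weighted ancestry
    covariance with genetic distance. Includes post-processing of
    identity-by-descent segment tables (minimum-length filtering, gap
    merging under a discordant-homozygote rule, per-pair aggregation)
    and a synthetic-data generator (drift trees, dated and sex-biased
    admixture pulses, pseudohaploid sampling with terminal deamination
    damage, ancestry tracts, IBD fixtures) so that every stage of the
    pipeline can be validated without access to restricted genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
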