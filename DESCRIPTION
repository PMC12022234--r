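Package: nivgeno
Title: Quality-Controlled Microsatellite Genotyping from Noninvasive Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A standardized framework for long-term genetic monitoring of
    elusive wildlife from noninvasively collected samples (scat, urine, hair),
    as applied to large-scale gray wolf (Canis lupus) monitoring. Implements
    the multitube approach end to end: species and mitotype screening of
    mitochondrial control-region sequences against an offline reference
    panel, per-sample consensus genotypes from replicated microsatellite
    amplifications with contamination flagging, Miquel-style quality indices
    and quality filtering, individual identification by genotype matching
    under a binomial mismatch model, staged allelic-dropout and false-allele
    rate estimation (initial, high-quality, residual), probability of
    identity among siblings over locus subsets, and population diversity
    statistics (allele counts, heterozygosities, FIS, Hardy-Weinberg
    permutation tests, null-allele maximum likelihood). A synthetic-data
    simulator with complete truth logs makes every stage testable, including
    parameter-recovery and clustering-accuracy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
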