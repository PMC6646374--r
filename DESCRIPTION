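Package: lethalscan
Title: Screening Multi-Population Genotype Panels for Potentially Lethal Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bi-allelic SNPs whose genotype distributions are
    incompatible with random mating because one genotype class is entirely
    absent from every sampled population despite a non-trivial expected
    count. For each shared SNP the random-mating (Hardy-Weinberg)
    next-generation genotype distribution is computed from the observed
    genotype frequencies, the binomial probability that the missing class is
    never observed is evaluated per population, evidence is combined across
    populations by multiplying the per-population probabilities in log
    space, and SNPs are flagged after a Bonferroni correction over all
    genotype-class hypotheses. Includes readers and writers for HapMap
    phase-3-style genotype files, a harmonization step that intersects SNPs
    across populations with strand reconciliation, a per-chromosome and
    genome-wide screening driver, and a seeded synthetic-panel simulator
    with genotype-specific viability selection for type-I-error and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
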