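Package: genodegrade
Title: Degrade Simulated Genotypes with Empirical Missingness Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns idealized simulated genotypes (phased, polarized,
    complete) into realistic ones by replicating both the distribution and
    the positional dispersal of fully-missing genotypes observed in an
    empirical template dataset, or by drawing per-site missingness
    proportions from a moment-matched beta distribution. Additional
    degradation operators remove phase and ancestral-allele polarization,
    introduce post-mortem deamination damage, and pseudohaploidize
    genotypes, as is standard when emulating low-coverage ancient DNA.
    Includes readers and writers for VCF, Hudson ms-style simulator
    output, and EIGENSTRAT triplets, PLINK-style missingness summaries,
    and histogram/Kullback-Leibler divergence evaluation of how well a
    degraded dataset reproduces a template's missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
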