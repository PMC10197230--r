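Package: snpanel
Title: Multi-Species SNP Array Design and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing and validating medium-density SNP
    genotyping arrays spanning several closely related, hybridizing
    species, as developed for blue mussel (Mytilus) 60 K class arrays.
    Covers hard filtering of called variants, allele-frequency and
    missingness filters, linkage-disequilibrium pruning, PCA and a
    binomial-likelihood admixture model for species assignment,
    flanking-monomorphism probe screening with 71-mer extraction,
    sharing-tier panel assembly with per-species quotas and prior
    marker sets, and array validation through call-rate scenarios,
    polymorphism reports and cross-platform genotype concordance.
    Includes a multi-species hybrid-zone genotype simulator so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
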