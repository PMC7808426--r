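Package: triocit
Title: Host Genetics, Gut Microbiome and Metabolome Integration with
    Causal Inference Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integration pipeline for case-control cohorts with host
    exome variants, gut metagenome abundance profiles, fecal metabolite
    intensities and serum cytokine panels. Provides rare-variant triage
    against population allele-frequency databases, trinucleotide mutation
    spectra, genotype and microbiome principal component analysis with
    Simpson alpha-diversity correlation, covariate-adjusted association
    screens with Benjamini-Hochberg false discovery rate control,
    Mann-Whitney and PLS-DA/VIP differential-abundance rules, and a
    four-condition causal inference test that classifies
    variant-microbe-metabolite trios as causal, reactive, independent or
    ambiguous. A seeded synthetic-cohort generator with an embedded-effect
    truth ledger supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
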