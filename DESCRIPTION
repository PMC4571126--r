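Package: expansionclock
Title: Molecular Rate Calibration from Mismatch Distributions Under Sudden
    Population Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and dating sudden demographic expansions from
    haploid (mitochondrial) sequence alignments, and for calibrating molecular
    evolutionary rates against paleoclimatic expansion times. Implements
    diversity summaries (nucleotide and haplotype diversity, segregating
    sites), Kimura two-parameter distances, Tajima's D and Fu's Fs neutrality
    tests with coalescent-simulation p-values, least-squares fitting of the
    sudden-expansion (Rogers-Harpending) mismatch distribution model with
    parametric-bootstrap goodness of fit, conversion of the expansion
    parameter tau into evolutionary rates via t = tau/(2u) with u = mu*k*g,
    strict-clock UPGMA dating, and a seeded coalescent simulator of
    instantaneous-expansion demographies with finite-sites or infinite-sites
    mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
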