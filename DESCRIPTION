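Package: twinconn
Title: Twin-Based Heritability and Fingerprinting of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of twin-pair functional connectomes: correlation-based
    individual and twin identification (connectome fingerprinting) with
    permutation significance, nonparametric effect sizes (Cliff's delta)
    across relatedness groups, and heritability of functional-network
    connectivity via a bootstrapped multivariate ACE variance decomposition
    with zygosity-shuffled null distributions. Includes a synthetic twin-cohort
    generator with known additive-genetic, shared-environment and unique
    variance structure so the full pipeline is testable without restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
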