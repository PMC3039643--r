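Package: mshybrid
Title: Multilocus Diagnostics for Hybrid Zones of the Anopheles gambiae
    M and S Molecular Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genetic analysis of diagnostic marker panels in
    hybrid zones between the M and S incipient species of Anopheles
    gambiae sensu stricto.  Provides per-locus Hardy-Weinberg exact
    tests by complete enumeration of the Levene conditional
    distribution, Weir-Cockerham within-sample inbreeding coefficients,
    EM estimation of two-locus haplotype frequencies with linkage
    disequilibrium statistics (D, D', r2) and permutation likelihood
    ratio tests, joint-genotype association classification
    (parental/assorted/congruent and IGS-versus-SINE mismatch
    taxonomies), quantitative scoring of dual electropherogram peaks as
    rDNA copy-number proportions, and a seedable synthetic hybrid-zone
    generator with closed-form Wahlund expectations for testing every
    stage from scratch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
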