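Package: neostrat
Title: Metagene Stratification and Paired Pre/Post-Treatment Genomics for
    Neoadjuvant Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chemotherapy response in HER2-negative
    breast cancer. Associates gene expression with a semi-continuous
    response index through a permutation-based moderated regression
    statistic with false-discovery-rate control, stratifies patients into
    HHL/LLH profiles from three median-based metagenes (proliferation,
    immune response, extracellular matrix organization), compares
    recurrence-free survival between profiles (Kaplan-Meier, log-rank,
    two-group Cox), and contrasts paired pre/post-treatment genomes via
    purity-adjusted copy-number deltas, delta segmentation, and
    somatic-variant sharing. Includes a synthetic cohort generator that
    plants the latent structure the analysis assumes, so every stage is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
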