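Package: growfda
Title: Functional Data Analysis of Individual Growth Variability in Bivalves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing inter-individual growth variability and
    its physiological drivers in longitudinally sampled bivalves. Computes
    scope-for-growth energy budgets from feeding, digestion and metabolic
    rates; turns repeated individual measurements into smooth curves by
    Nadaraya-Watson kernel smoothing with generalized cross-validation;
    detects atypical individuals via h-modal functional depth with a
    trimmed-mode bootstrap cutoff; and compares fast and slow growers with a
    bootstrap one-way functional ANOVA, a distance-covariance permutation
    test, and distance-based dispersion tests. Includes a synthetic cohort
    generator emulating a monthly-sampled mussel culture so the full pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
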