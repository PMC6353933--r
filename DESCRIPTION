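Package: vhratio
Title: Virus-Host Abundance Scaling and Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for re-analysing virus-host abundance relationships in
    marine metagenomes. Fits power-law (log-log) slopes between virus and
    host relative abundances, diagnoses spurious self-correlation in
    ratio-versus-denominator regressions (the -1 null slope), builds
    permutation null distributions with two-tailed p-values and randomized
    percentile confidence intervals, applies family-wise (Bonferroni)
    correction across virus-host pairs, and generates synthetic abundance
    collections with known power-law coupling, lognormal noise and
    zero-inflation for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
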