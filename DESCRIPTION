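Package: mitoburden
Title: Mitochondrial DNA Heteroplasmy Burden Analysis for Matched Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of mitochondrial DNA (mtDNA) whole-genome variant
    tables from matched case-control cohorts sampled at two visits.
    Implements dual-caller consensus variant filtering with a curated-database
    rescue path for low-level heteroplasmies, rCRS region and macro-region
    annotation, pathogenicity-weighted burden scores (cumulative deleterious
    burden, region-size-adjusted mutational, deleterious and MitoTIP rates),
    paired cross-sectional statistics (exact McNemar on discordant pairs,
    paired t-tests, Kruskal-Wallis haplogroup tests, Monte Carlo Fisher
    tests, Benjamini-Hochberg FDR), longitudinal transient/persistent
    heteroplasmy dynamics, a matched-pair power calculation by trinomial
    enumeration, and a seeded synthetic triplet-cohort generator with a
    ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
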