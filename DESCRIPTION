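Package: aspnmr
Title: Detecting Aspartate Isomerization and Asp-Xaa Backbone Cleavage in
    Denatured Proteins from 2D NMR Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify spontaneous aspartate degradation
    products (isoaspartate, succinimide, and backbone cleavage after Asp) in
    denatured proteins from 1H-13C HSQC peak lists. Provides a pH-aware
    random-coil chemical-shift reference library with uniqueness scoring of
    diagnostic cross-peaks, one- and two-site Henderson-Hasselbalch titration
    models with nonlinear pKa fitting and bootstrap confidence intervals,
    Sparky and CSV peak-list import/export with DSS-based indirect
    rereferencing, rule-based modification calling with integral-based
    stoichiometry estimates, and seeded synthetic-data generators used as
    ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
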