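Package: gpool
Title: Preliminary Screening of Questionnaire Items for Item Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Flags problematic or inefficient questionnaire items before any
    factor solution is fitted. Items are placed in extremeness-by-consistency
    coordinates (the item mean in proportion metric against the square root
    of the squared multiple correlation) with bootstrap confidence intervals,
    and compared against an appropriateness region derived by simulation.
    Per-item measures of sampling adequacy (MSA), prior item efficiency (PIE)
    and its normed version (R-PIE) support a two-step selection of an
    efficient, problem-free item subset. Includes Pearson and two-step
    polychoric correlation engines with positive-definiteness diagnostics,
    one-factor unweighted least squares extraction, and a Monte-Carlo study
    of ordinal one-factor data that calibrates the appropriateness region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
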