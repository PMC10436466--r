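Package: tilrep
Title: TCR Repertoire Analysis of CD4+ and CD8+ Tumor-Infiltrating
    Lymphocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare T-cell receptor (TCR) repertoires of CD4+ and
    CD8+ tumor-infiltrating lymphocytes from clonotype tables: CDR3 and
    N(D)N length statistics, frequency-weighted physicochemical profiles of
    the central CDR3 5-mer, normalized Shannon-Wiener diversity, convergent
    recombination, public-clonotype analysis, GLIPH2-style CDR3 motif
    discovery with Fisher and clonal-expansion scoring, and edit-distance
    annotation against a TCR specificity database. Includes a seeded
    synthetic V(D)J repertoire generator with controllable junction length,
    charge bias, clone-size law, convergence, publicity and planted motifs,
    so every stage is testable without sequencing data, plus an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
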