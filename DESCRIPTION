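Package: triocnv
Title: Consensus Copy-Number Variant Calling and De Novo Classification
    for Case-Parent Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for copy-number variants (CNVs) called
    from whole-exome sequencing of case-parent trios by multiple read-depth
    callers. Standardises heterogeneous caller outputs into a common BED-like
    table, derives high-confidence consensus CNVs by reciprocal-overlap
    agreement between callers, classifies proband CNVs as de novo or
    inherited against parental call sets, applies ACMG-class and
    Exomiser-score prioritisation gates to annotation tables, and summarises
    cohorts (per-tool counts, size distributions, consensus overlap rates,
    paired signed-rank tests for deletion/duplication bias). Includes a
    synthetic trio-cohort simulator that emulates imperfect callers with
    ground-truth bookkeeping, so the whole pipeline is testable end to end
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
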