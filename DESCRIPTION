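Package: variantql
Title: Query Annotated VCF Cohorts with a Variant Query Language
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Imports annotated multi-sample VCF files (SnpEff ANN or VEP CSQ
    annotations) together with optional PED pedigrees into an embedded
    normalized variant store, and filters them with VQL, a small SQL-like
    variant query language. Multi-allelic records are decomposed to one row
    per alternate allele, genotypes are recoded to 0/1/2 dosage codes, and
    per-variant case/control genotype counts are materialized at import so
    cohort filters are plain field comparisons. Supports named selections
    with set algebra, gene wordsets, BED interval intersection, trio
    transmission-mode filters, sorting, CSV export and a headless
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
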