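Package: neoforge
Title: Proteogenomic Neoantigen Discovery from Somatic Variants and
    Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for tumor neoantigen discovery from
    somatic variants, transcript expression and HLA class I immunopeptidome
    data. Builds personalized proteogenomic search databases (canonical
    proteome plus expression-gated mutation windows), enumerates candidate
    8-11mer neoantigens with percentile-rank MHC binding filtering through a
    pluggable scorer, performs simplified no-enzyme MS/MS identification with
    b/y fragment matching and concatenated target-decoy q-values, compares
    tumor and normal ligandomes to nominate overexpressed nonmutated
    tumor-associated antigens, quantifies downstream assay readouts (pHLA
    stabilization, 4PL functional avidity, LDH cytotoxicity, variant allele
    frequency), and summarizes TCR-beta clonotype expansion. A seeded
    synthetic-data module generates every input format so the full analysis is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
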