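Package: nearloh
Title: Allele-Specific Copy Number and Near Copy-Neutral LOH Analysis for
    SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing allele-specific SNP-array profiles of
    contaminated, polyploid tumour samples.  Estimates stromal
    contamination and ploidy by grid search over a tumour-normal mixture
    model, assigns integer allelic states (major+minor copies) to
    segments of constant signal, classifies loss-of-heterozygosity events
    into a taxonomy built around "near copy-neutral LOH" (LOH at least
    partially compensated by the remaining allele, judged relative to the
    sample's overall ploidy), and compares event burden and subtype
    spectra between sample groups with exact nonparametric tests.  A
    synthetic-cohort generator with known ground truth makes the whole
    pipeline testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
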