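Package: mitopair
Title: Matched Blood-Tumor Mitochondrial DNA Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of whole mitochondrial genome variants observed in
    matched blood-tumor pairs. Classifies variants into germline, somatic and
    probable-mutation classes by mutant allele fraction (MAF) thresholds,
    calls heteroplasmy and homoplasmy, quantifies blood-to-tumor heteroplasmy
    shifts, annotates strand-aware protein consequences under the vertebrate
    mitochondrial genetic code on the rCRS coordinate frame, computes per-gene
    mutation rates and cohort summaries stratified by breast tumor subtype,
    scores haplogroups against a marker panel, and estimates survival
    differences by somatic mutational burden (Kaplan-Meier, log-rank, Cox).
    Includes a synthetic matched-pair cohort generator with recorded ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    vegan,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
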