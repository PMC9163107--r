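Package: rnasomatic
Title: Somatic Variant Classification from Tumor RNA-Seq Without a
    Matched Normal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies single-nucleotide variants called from tumor
    RNA sequencing into somatic mutations and germline variants when no
    matched-normal sample is available.  A 31-feature random-forest
    ensemble (read counts, caller likelihood, germline-database presence
    and allele frequencies, and panel-of-normals allele-fraction
    histograms with a beta-slice likelihood score) is trained fold-wise
    on labeled cohorts and applied by majority vote; predicted somatic
    calls are then cleaned by an RNA-specific filter chain (editing
    sites, sequencing leakage, duplicate supporting reads, pseudogenes,
    population-frequency and panel-of-normals filters).  Also provides
    a beta-binomial detection-power model, per-sample precision/recall
    evaluation, RNA-based tumor-mutational-burden survival
    stratification, and a synthetic-cohort simulator for end-to-end
    exercise without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
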