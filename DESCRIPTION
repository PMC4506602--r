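Package: netpharm
Title: Network Pharmacology Screening of Herbal Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-pharmacology pipeline for identifying bioactive
    constituents of multi-herb formulas. Merges per-herb compound catalogs
    from multiple sources with provenance-aware deduplication, screens
    compounds by Lipinski's rule of five, oral bioavailability and a
    Tanimoto drug-likeness index, filters compound-protein interactions by
    confidence score and ranks compound-gene interactions by occurrence
    frequency, performs Fisher's exact gene-set enrichment with
    Benjamini-Hochberg correction and a random-walk-with-restart pathway
    proximity (XD-style) score, and intersects the druggable and
    disease-linked compound sets into a final candidate list. Includes a
    seeded synthetic-data generator with planted ground truth so every
    stage is testable end to end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
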