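Package: splicevet
Title: Vetting Expression Constructs for Cryptic Splice Donors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Epitope-tag fusions and other junctions in expression constructs
    can create cryptic splice donor sites that, in the presence of a
    downstream splice acceptor, cause aberrant splicing of the transgene
    pre-mRNA and loss of the intended protein product. splicevet detects and
    classifies splice-donor signals with a tiered consensus model, enumerates
    donor/acceptor-consistent splice isoforms of a construct and classifies
    the protein consequence of each, proposes synonymous codon repairs that
    destroy a donor without changing the encoded protein, screens CDS
    libraries for tag-fusion junctions that create donors, and predicts
    diagnostic restriction-digest fragment patterns. Deterministic synthetic
    fixtures reproduce the geometry of a tagged ORF upstream of a two-intron
    3' region so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
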