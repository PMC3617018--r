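Package: chromdiverge
Title: Comparative Divergence of Higher Order Chromatin Structure Between Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects regions of the mammalian genome whose higher-order chromatin
    structure (replication timing, nuclear lamina association, Hi-C compartment
    eigenvalues) has diverged between two species. Probe-level or pre-binned signal
    tracks are averaged into fixed 100 Kb bins, paired across species by reciprocal
    best coordinate overlap, and quantile normalised across assay platforms.
    Divergent bins are called with a SAM-style moderated two-class permutation
    statistic under median-false-positive FDR control, clustered into maximal
    same-polarity runs assessed against a within-chromosome permutation null, and
    tested for positional enrichment (subtelomeric, centromeric, arbitrary interval
    sets) by circular permutation. Downstream statistics relate divergence to GC
    content, gene density, orthologous expression divergence and chromosome
    distribution. A synthetic-data module generates two-species multi-dataset
    chromatin landscapes with known ground truth so the whole pipeline runs and is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
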