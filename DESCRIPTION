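Package: dosagelens
Title: Fragment-Size-Resolved ChIP Profiling and Cross-Species
    Dosage-Compensation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for facultative dosage compensation studies:
    MNase ChIP-seq fragment-size partitioning (sub-nucleosomal footprints
    versus nucleosome-scale fragments), binned genome coverage with
    input-normalization modes that exclude the X chromosome from scaling,
    reference-point and scaled-gene-body signal matrices, peak merging and
    TSS assignment, chromosome overrepresentation tests, k-means clustering
    of multi-track peak signal, FLASH (RNA crosslinking) read processing
    with barcode demultiplexing and random-tag PCR-duplicate removal,
    qPCR relative quantification with efficiency correction, and a
    bootstrap gene-set test with Benjamini-Hochberg correction for
    cross-species orthologue dosage sensitivity. Includes a synthetic-data
    generator that plants ground truth (high-affinity sites, footprint and
    nucleosomal fragment classes, X monosomy, PCR duplication, expression
    shifts) so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
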