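Package: septolink
Title: Gene-Neighborhood Linkage of Septal Hydrolase Regulators and
    Single-Cell Septal Fluorescence Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of bacterial cell-division
    genes. The comparative-genomics half defines gene families by boolean
    queries over PFAM/KEGG/TIGRFAM annotation labels, computes per-genome
    copy-number (phyletic) profiles, and quantifies gene-neighborhood linkage
    between two families as the per-genome closest pair on a shared replicon,
    with same-strand fractions and intergenic-distance histograms; results
    export as TSV and iTOL-style multibar datasets. The image-analysis half
    consumes integer label masks plus fluorescence images and measures, per
    cell, a medial-axis centerline (length and averaged width), normalized
    intensity profiles along the axis, length-sorted demographs, and a
    background-subtracted relative midcell intensity. Two synthetic-data
    generators (an annotated pangenome with planted operon-style linkage, and
    rendered rod-shaped cells with known geometry and signal models) provide
    ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    tiff,
    ape,
    EBImage,
    S4Vectors,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
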