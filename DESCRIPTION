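Package: bsascan
Title: Euclidean-Distance Genome Scans for Bulked Segregant Analysis
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping trait loci from pooled whole-genome
    sequencing of two phenotype-selected bulks (BSA-seq). Computes a
    per-SNP Euclidean-distance association statistic from per-base read
    frequencies of the two bulks, applies a noise-suppressing power
    transform, smooths the signal with sliding-window averages along the
    genome, and calls candidate regions where the fitted track exceeds
    three standard deviations above the genome-wide median. Includes
    variant proximity and locus filters for pooled variant calls, a
    synthetic two-bulk pooled-sequencing simulator (selfed F2-like
    population, Haldane map, Poisson depth, per-base sequencing error)
    for end-to-end testing and power studies, candidate-region gene
    annotation with Fisher's exact pathway enrichment against a
    genome-wide background, and cross-referencing with differentially
    expressed genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
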