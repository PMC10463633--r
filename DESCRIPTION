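Package: isobloom
Title: Isochore Segmentation and the GC Architecture of Tandem Gene Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relationship between regional AT/GC
    composition and tandemly arrayed gene families. Segments genomes into
    isochores by recursive GC-divergence splitting, computes per-gene GC
    features, metagene GC trajectories and promoter CpG observed/expected
    scores, classifies genes by iterative 3x3 k-means on their GC
    trajectories, measures gene-name-prefix (Shannon) diversity and tandem
    neighbour counts per isochore, overlays de novo mutation, crossover,
    PRDM9, rare-variant, expression-breadth and A/B-compartment signals,
    extracts syntenic tandem arrays across species from bookend orthologs
    with feature-level GC decomposition, and fits phylogenetic generalized
    least squares regressions of cluster GC on log paralog count with
    Pagel's lambda estimated by maximum likelihood. Includes a synthetic
    genome, annotation, event and species-panel generator so the whole
    pipeline runs end-to-end on simulated data with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nlme,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
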