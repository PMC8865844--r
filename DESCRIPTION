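Package: plasmap
Title: Spatial and Single-Nucleus Transcriptomics of Plasmodial Syncytia
Version: 0.1.0
Authors@R:
    person("Plasmap", "Developers", email = "maintainer@plasmap.dev",
           role = c("aut", "cre"))
Description: Analysis toolkit for spatially resolved and single-nucleus
    transcriptomics of syncytial slime-mold plasmodia. Provides point-pattern
    statistics for stained nuclei (shape descriptors, nearest-neighbour
    distances, kernel density maps, an unbiased Otsu split of the density
    profile into growth-front and network regions, and detection-quality
    scoring), gridded-transcriptome processing (TPM and log-normalisation,
    depth and annotation filters, covariate-regression scaling, PCA, graph and
    hierarchical clustering, Wilcoxon marker detection, module scores),
    region-restricted differential expression and distance-versus-correlation
    statistics on sampling grids, pseudobulk Spearman projection of nuclei
    clusters onto spatial clusters, diffusion-map pseudotemporal ordering of a
    synchronised mitotic wave, and a seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
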