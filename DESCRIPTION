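Package: axonmap
Title: Mesoscale Projection Statistics from Single-Neuron Axonal Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates complete single-neuron axonal reconstructions registered to a
    common brain atlas into mesoscale connectivity statistics. Reads SWC and a
    portal-style JSON morphology dialect, normalizes coordinates to the atlas
    orientation, reduces each axonal tree to its topological minor, and measures
    per-area and per-layer terminal branch length, dominant projection targets,
    projection motifs and their binomial-test significance. Computes an unbiased
    pairwise morphological dissimilarity with a rotation-only rigid Coherent Point
    Drift registration, embeds the dissimilarity matrix in two dimensions, derives a
    one-dimensional morphological gradient from geodesic distances in the embedding,
    and quantifies soma-to-terminal topography with a least-squares transform, polar
    decomposition and Euler angles. Includes a synthetic-population generator with
    known ground truth so that every pipeline stage is testable without downloading
    the public morphology archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    yaml,
    RNifti,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
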