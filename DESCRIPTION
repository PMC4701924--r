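Package: voxelgraph
Title: Out-of-Core Voxelwise Functional Connectivity Graphs from fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds voxelwise functional connectivity graphs from 4D NIfTI
    resting-state fMRI data on a single machine with bounded memory. Reads
    masked BOLD time series in volume chunks, computes the full voxelwise
    Pearson correlation matrix in row-block tiles under an explicit byte
    budget, streams threshold-surviving entries to a sparse edge list, and
    derives per-voxel graph metrics (degree, connected components, triangle
    counts, local clustering coefficient, PageRank) written back as NIfTI
    maps. Includes edge-density-based automatic threshold selection, group
    stacking of subjects with a randomized truncated SVD, and a synthetic
    BOLD generator with planted community correlation structure for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
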