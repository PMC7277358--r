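Package: splicedyn
Title: Network Prioritization and Trajectory Dynamics of the SF3B1 K700E
    Spliceosome Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for a molecular-dynamics study of the SF3B1
    K700E cancer hotspot mutation in the SF3b spliceosome complex.
    Builds a pre-mRNA-splicing gene network from STRING-style edge lists,
    computes closeness/radiality/eccentricity centralities, filters
    COSMIC-style somatic-mutation tables by FATHMM pathogenicity, and
    ranks genes and amino-acid changes. Provides trajectory descriptors
    (Kabsch superposition, RMSD, RMSF, minimum distances, cutoff contact
    counts), essential dynamics (principal component analysis of the
    C-alpha positional covariance matrix, variance fractions, 2D
    projections, per-mode RMSF), and dynamic cross-correlation maps with
    region-block summaries. A synthetic-data module generates
    mode-structured, block-correlated and contact-kinetics trajectories
    plus network/mutation fixtures with known ground truth, so every
    stage is verifiable without multi-microsecond simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
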