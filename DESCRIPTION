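Package: subfold
Title: Conformational Ensembles from Subsampled Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for predicting and analysing protein conformational
    ensembles obtained by subsampling multiple sequence alignments before
    structure prediction. Implements the cluster-center subsampling
    heuristic (max_seq centers, Hamming-distance assignment, extra_seq
    sampling), prediction-run manifests over replicates, seeds and models
    with a pluggable predictor backend, ensemble analysis (backbone RMSD
    projection onto reference states, state binning, relative state
    populations with across-replicate standard errors, structural
    observables, unfolded-structure detection, subsampling-parameter
    scans), comparison of predicted ensembles against molecular-dynamics
    snapshot series, and fully synthetic fixture generators with known
    ground truth for end-to-end testing without a neural-network predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
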