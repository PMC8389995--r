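Package: mrse
Title: Multiscale Reweighted Stochastic Embedding of Enhanced-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional collective variables from enhanced-sampling
    simulation data by training a parametric, multiscale, reweighted stochastic
    neighbor embedding on weight-tempered landmarks. Includes a self-contained
    well-tempered metadynamics simulator on the Mueller-Brown potential that
    produces biased trajectories with statistical weights, weight-tempered
    random landmark selection, perplexity-matched reweighted Gaussian kernels,
    a deep neural-network embedding trained with a Kullback-Leibler loss,
    reweighted kernel density free-energy surfaces, Procrustes alignment and
    distance-preservation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
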