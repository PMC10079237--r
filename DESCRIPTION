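Package: wpcf
Title: Weighted Pair Correlation Functions and Spatial Signatures for
    Tumour-Macrophage Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial statistics for 2D point patterns carrying both categorical
    labels and continuous marks, as produced by multiplex-image cell
    segmentations or agent-based simulations. Implements the weighted pair
    correlation function (wPCF), which resolves spatial correlation as a
    continuous function of a point's mark (for example macrophage phenotype),
    together with the cross-type pair correlation function with exact
    border correction. Includes an off-lattice, force-based agent-based model
    of tumour growth with blood vessels, five diffusible signalling fields and
    macrophages whose phenotype evolves continuously from anti-tumour to
    pro-tumour, and a classification pipeline that summarises snapshots as
    PCF signatures, reduces them by principal component analysis and labels
    them as tumour Equilibrium, Escape or Elimination with a support vector
    machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    yaml
Config/testthat/edition: 3
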