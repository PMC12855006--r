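Package: omixae
Title: Configurable Autoencoder Framework for Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Omixae", "Developers", email = "omixae@example.org", role = c("aut", "cre"))
Description: A standardized, configuration-driven pipeline for preprocessing
    multimodal biological data (bulk and single-cell omics matrices,
    categorical annotations, square images), training five autoencoder
    architectures (vanilla, variational, stacked, ontology-masked and
    cross-modal with adversarial latent-space alignment), and evaluating the
    resulting embeddings with reconstruction R-squared, latent-space coverage,
    total correlation, downstream machine-learning Z-scores and repetition
    robustness. Includes a synthetic multi-omics generator with planted latent
    factors, ontologies and class-conditioned images so that every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    png,
    rhdf5,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
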