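Package: latentrc
Title: Latent-Space Reverse Correlation for Individual Face Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reverse-correlation experiments carried out in the
    latent space of a face generator. Builds stimulus pools by averaging
    random subsets of latent codes and adding Gaussian noise, models
    three-alternative (target / opposite / neither) categorization sessions,
    fits per-participant directional-vector models with intensity
    extrapolation, computes inter-participant agreement of extrapolated
    representations, and partitions cross-classified rating variance into
    shared (stimulus) and idiosyncratic (participant, participant-by-stimulus)
    components. Includes a synthetic-data generator (structured latent pools,
    simulated observers, ratings with known variance components) and a
    deterministic mock renderer so the full pipeline is testable without a
    trained generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
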