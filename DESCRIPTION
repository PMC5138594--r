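Package: edgecamo
Title: Edge-Enhanced Disruptive Camouflage Stimuli and Bayesian Search Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates edge-enhanced disruptive camouflage stimuli and analyses
    visual-search performance against them. Builds leaf-litter background
    scenes with optional cast shadows, synthesises two-tone camouflage
    textures from Fourier band-pass filtered noise posterised at the median,
    applies a two-parameter (offset, width) luminance edge-enhancement model
    in four variants, enumerates balanced factorial search and
    depth-judgement designs, simulates observer behaviour with a log-normal
    reaction-time model, and analyses results with control-relative z-scored
    log reaction times, bootstrap confidence intervals, Shapiro-Wilk checks
    and JZS (Cauchy-prior) Bayes-factor t-tests with Jeffreys evidence
    labels. Also profiles luminance transects across pattern boundaries in
    photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    withr,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    tiff
Config/testthat/edition: 3
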