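Package: wspray
Title: Droplet Deposition Analysis on Water-Sensitive Paper
Version: 0.1.0
Authors@R:
    person("wspray", "maintainers", email = "wspray@example.org",
           role = c("aut", "cre"))
Description: Segments spray droplet stains on scanned water-sensitive paper
    (WSP) and computes deposition coverage and density. Implements three
    global thresholding methods - a fixed 8-bit threshold, exhaustive Otsu
    maximisation of between-class variance, and a seeded genetic-algorithm
    search of the same Otsu objective - followed by morphological closing to
    repair glare holes, connected-component droplet counting, and
    pixel-area-based sparse/medium/dense grouping. A synthetic WSP generator
    with exact ground truth supports benchmarking of relative errors in
    coverage and density, and a command-line front end ties analysis,
    simulation and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
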