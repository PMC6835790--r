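Package: lpland
Title: Liking Product Landscapes for Consumer Hedonic and Just-About-Right Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds liking product landscape (LPL) maps from consumer sensory
    panels. Consumers rating a product set on a 9-point hedonic scale and
    5-point just-about-right (JAR) attribute scales are embedded in a 2-D map
    (internal preference mapping, principal components, or metric
    multidimensional scaling), their distribution is estimated by Gaussian
    kernel density with the Scott-rule bandwidth, and per-evaluation
    acceptance surfaces are fitted over the map by a quadratic model or
    support-vector regression and scored by a scale-normalized percentage
    error. Includes a two-segment panel simulator, a benchmark of the
    fourteen technique/data combinations, Ward-linkage consumer segmentation,
    composite landscape figures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
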