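Package: marbeta
Title: Global Beta-Diversity Analysis of Marine Bacterial Communities
Version: 0.1.0
Authors@R: person("marbeta", "developers", role = c("aut", "cre"),
    email = "marbeta@example.org")
Description: Tools for analysing beta-diversity of marine bacterial OTU
    tables across pelagic and benthic realms and their ecosystems:
    Hellinger standardization, Bray-Curtis dissimilarities, non-metric
    multidimensional scaling, ANOSIM permutation tests, multivariate
    dispersion, Procrustes/PROTEST comparison of ordinations, shared-OTU
    resampling, distance-based redundancy analysis and variation
    partitioning with adjusted R-squared, plus a synthetic community
    generator that emulates the statistical structure of a global marine
    pyrotag survey (two realms with low OTU overlap, singleton-rich
    abundance distributions, spatial distance decay, productivity and
    time covariates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
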