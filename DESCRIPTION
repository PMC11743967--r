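Package: phenorec
Title: Digital-Phenotyping Well-Being Profiles and Exercise Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a chatbot-based digital-phenotyping
    well-being program: simulates a trial cohort with planted behavioral
    profiles, encodes mixed-type baseline and interaction-log data into a
    weighted unit-scaled feature table, performs soft K-medians clustering
    under a weighted Manhattan metric with silhouette model selection,
    explains cluster membership with Shapley feature contributions, and
    ranks well-being exercises for a test participant by a cluster-weighted
    normalized utility-deviation score.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
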