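Package: psokm
Title: Hybrid Particle Swarm and K-Means Clustering for Tibial Rotation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters subjects by physical characteristics (age, weight,
    height) using K-means hybridized with particle swarm optimization
    (PSO-KM): particles encode candidate centroid sets, the swarm minimizes
    the clustering sum of squared errors, and K-means refines the swarm
    optimum. Includes rule-based anthropometric cluster assignment and
    tibial-rotation pathology typing (Type 1 pathological <= 20 degrees,
    Type 2 normal, Type 3 pathological > 65 degrees), external validity
    arithmetic (success rates, type rates, general accuracy, Rand index),
    a seeded synthetic cohort generator, and an end-to-end evaluation
    pipeline comparing PSO-KM against plain K-means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
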