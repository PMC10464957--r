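Package: reddmap
Title: Semi-Automated Mapping of Salmonid Spawning Redds in UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pixel-based supervised-classification pipeline for mapping
    salmonid spawning redds (gravel nests) in low-altitude drone RGB imagery
    of lake spawning grounds. Implements Gaussian maximum-likelihood and
    one-hidden-layer logistic neural-network classifiers parameterised from
    analyst-drawn training regions of interest, the three standard spatial
    post-classification operators (majority/minority kernel filtering, sieve
    removal of sub-minimum connected components, and morphological clumping),
    and thematic accuracy assessment via ground-truth confusion matrices with
    producer's, user's and overall accuracy and the kappa coefficient. A
    seeded synthetic lake-scene generator emulates the six-endmember scene
    structure of subarctic spawning grounds so the full pipeline is testable
    without drone data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
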