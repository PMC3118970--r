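Package: vertegrow
Title: Growth-Modulated Simulation of Spinal Deformity Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale biomechanical simulation of vertebral column growth
    during adolescence under Hueter-Volkmann (Stokes) growth modulation.
    Builds parametric T1-L5 spine geometries with layered growth plates,
    applies Schultz-type gravity or follower loading, computes growth-plate
    stress fields by composite-section equilibrium, and iterates
    stress-modulated growth to follow coronal Cobb, kyphosis, lordosis and
    axial rotation over ages 8-18. Includes the six-case comparison of
    adolescent idiopathic scoliosis (AIS) versus normal growth-velocity
    profiles and the associated sensitivity analyses (growth sensitivity
    constant, loading configuration, growth-velocity scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
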