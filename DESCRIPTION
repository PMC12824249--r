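Package: fabmotion
Title: Motion Recognition and Prediction from Rigid- and Fabric-Attached
    Sensors with Left-to-Right Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising and predicting movement from multichannel
    motion-capture trajectories recorded simultaneously on a rigid body and on
    loose fabric attached to it. Fits left-to-right hidden Markov models with
    one Gaussian state per time step by the Baum-Welch algorithm, classifies
    movements from trajectory prefixes by forward-algorithm likelihoods,
    predicts future rigid-body motion from Viterbi-ordered emission densities,
    and quantifies the discriminative information carried by each sensor
    channel with the cross-fitness distance between fitted models. Includes
    synthetic generators (scotch-yoke harmonics with a driven mass-spring-
    damper fabric proxy, rotated point-to-point patterns, minimum-jerk
    reaching) and the preprocessing steps used for wearable motion capture:
    cubic-spline gap filling, threshold onset alignment, orientation
    standardisation, baseline correction and fixed-length resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
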