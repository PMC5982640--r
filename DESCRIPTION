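Package: rehabmm
Title: Hidden Markov Model Assessment of Therapeutic Movements from
    Skeletal Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic quality assessment of physical rehabilitation
    exercises from depth-camera skeletal streams. Reads 25-joint skeletal
    trials, re-expresses motion in a body-anchored personal coordinate
    system, extracts buffered kinematic features (joint angles, linear and
    angular speeds, rotations), trains ensembles of Gaussian-emission
    hidden Markov models (Baum-Welch, forward, Viterbi, BIC state-count
    selection), and derives symmetry, synchronicity and compensation
    statistics that discriminate correct from faulty executions of
    therapeutic movements such as hip abduction. Includes a seeded
    synthetic-trial generator with injectable movement faults and a
    command-line front end for simulation, training and assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
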