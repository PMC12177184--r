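Package: katyjump
Title: Targeted-Jump Kinematics, Energetics and Ballistic Flight
    Simulation for Jumping Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of two-dimensional digitized point-tracking data of
    insect jumps toward overhead targets: jump event detection, take-off
    linear and angular velocity estimation, femorotibial joint angles,
    rigid-rod kinetic-energy budgets, a rigid-beam null model coupling
    linear and angular velocity, a ballistic flight-plus-rotation
    simulator for inverted overhead landings, a synthetic-study generator
    with known ground truth, and animal-stratified permutation tests for
    target-height effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
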