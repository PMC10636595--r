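Package: subgoalsim
Title: Grid-World Reinforcement Learning and Escape-Trajectory Analysis for
    Obstacle-Edge Subgoal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates shelter-directed escape learning in a 13x13 grid-world
    arena with eight reinforcement-learning agent families (tabular Q-learning,
    SARSA, successor representation, tile coding, immediate and gradual
    model-based planners, hierarchical state-space learners, and a dual
    Q-learning/model-based system) across four experimental conditions
    (obstacle removal, no-shelter training, full and partial one-way trip
    wires), and classifies the resulting escape routes. Also provides the
    behavioral quantification pipeline for continuous mouse-style trajectories:
    kinematics, escape target scoring, spontaneous homing- and edge-vector-run
    extraction, initiation-set logistic regression with McFadden pseudo-R2 and
    permutation p-values, AIC model comparison, pooled-mean-difference
    permutation tests, and a Von Mises classification-bias simulation, together
    with a synthetic-session generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
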