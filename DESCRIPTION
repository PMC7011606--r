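Package: crilearn
Title: Multi-View Action Classification and Child-Robot Interaction Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the cyber side of robot-assisted pediatric motor
    rehabilitation. Classifies a young child's gross-motor actions (crawling,
    sitting, standing, walking) from synchronized multi-camera video using
    short dense trajectories, Fisher-vector encoding and linear support vector
    machines, fusing the five camera views either by majority vote or by a
    multiple-instance SVM over view-bags. Models play-based child-robot
    interaction as a four-state Markov decision process with transition
    probabilities learned from sparse observations (maximum likelihood or
    additive smoothing), computes optimal robot policies by value iteration,
    and scores sessions by time-normalized accumulated utility. Includes
    seeded synthetic scene and child-behavior simulators so the full pipeline
    is testable without restricted video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
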