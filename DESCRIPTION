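Package: dqloc
Title: Deep Q-Learning Refinement of Lesion Boundary Keypoints in Retinal OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Locates the left and right lateral boundary points of a serous
    fluid lesion (neurosensory retinal detachment) on optical coherence
    tomography B-scans and measures the lesion chord diameter. A coarse
    initializer (a heuristic dark-blob detector or a small multitask
    convolutional network) proposes both keypoints; a per-side deep
    Q-learning agent then refines each point inside a local active region,
    treating localization as a Markov decision process over stacked image
    patches with four unit-step actions and a distance-decrease reward.
    Includes DQN, double-DQN and dueling variants, a synthetic B-scan
    phantom generator with speckle noise for end-to-end evaluation,
    BM3D/NLM/median denoising, and keypoint metrics (average Euclidean
    distance, correction rate, per-patient diameter summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
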