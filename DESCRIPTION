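Package: qcompose
Title: Hierarchical Behavior Composition by Arithmetic on Action Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how a novel composite
    behavior can be assembled from pretrained subtask policies by simple
    arithmetic on their action-value (Q) functions.  Provides a continuous
    object-to-target arena simulator with subtask and composite variants, a
    soft actor-critic (maximum-entropy reinforcement learning) trainer with
    twin critics whose pretrained subtask critics can be combined by averaging
    or by the elementwise maximum, and an analysis suite for agent and
    mouse-like data: state/action-value estimation from trajectories, policy
    fields and policy entropy, encoding models (GLM with raised-cosine bases),
    classification of Q-representing units with shuffle nulls and FDR control,
    selectivity and distribution indices, population-manifold comparison via a
    nearest-neighbor Kullback-Leibler divergence estimator, and a synthetic
    calcium-imaging-like session generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
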