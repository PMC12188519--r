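Package: qbcflow
Title: Asynchronous Query-by-Committee Active Learning for Machine-Learned Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An orchestration engine for active-learning workflows that build
    machine-learned interatomic potentials. Five decoupled kernels (prediction,
    generator, training, oracle, controller) exchange fixed-shape messages so
    that exploration by surrogate-driven molecular dynamics, ground-truth
    labeling, and committee retraining proceed concurrently; query-by-committee
    standard-deviation thresholding decides which configurations are labeled.
    Ships a deterministic single-process event-queue scheduler, closed-form
    demo oracles (Mueller-Brown surface, Lennard-Jones clusters) with analytic
    gradients, a Langevin/velocity-Verlet exploration generator with
    patience-based restarts, a small feed-forward committee regressor trained
    on energies and forces, extended-XYZ dataset input/output, checkpointing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
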