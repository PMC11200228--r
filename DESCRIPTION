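Package: augmem
Title: Sample-Efficient Reinforcement Learning for SMILES-Based De Novo
    Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Goal-directed molecular generation with an autoregressive
    SMILES language model fine-tuned by policy-gradient reinforcement
    learning. Implements the Augmented Memory algorithm, which reuses
    every oracle score across multiple policy updates by re-writing the
    sampled batch and the whole experience-replay buffer as randomized
    SMILES, together with REINVENT-style, Augmented Hill-Climb and
    Best-Agent-Reminder baselines, scaffold diversity filters with
    Selective Memory Purge, multi-parameter optimization scoring with
    oracle-call accounting, and budgeted-oracle evaluation metrics
    (AUC Top-10, internal diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
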