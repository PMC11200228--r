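# augmem

Sample-efficient reinforcement learning for SMILES-based de novo molecular
design, in pure R.

## What problem this solves

Goal-directed molecular generation fine-tunes a SMILES language model (the
*Agent*, initialized from a frozen *Prior*) so that sampled molecules
maximize a property oracle — a similarity model, QED, a docking score.
Because the oracle is the expensive step, methods are compared under a fixed
**oracle-call budget**. This package is for method developers and
computational chemists who want a compact, fully inspectable implementation
of budget-efficient SMILES RL with its standard baselines and metrics.

The core algorithm, **Augmented Memory**, reuses each oracle score for
several policy updates. For a molecule with reward $S(A) \in [0,1]$ the
Agent is regressed onto the augmented log-likelihood

$$\log P_{\text{aug}}(A) = \log P_{\text{prior}}(A) + \sigma\, S(A)$$

by minimizing the batch mean of
$\bigl(\log P_{\text{aug}} - \log P_{\text{agent}}\bigr)^2$. Each epoch
samples one batch, charges the oracle once, then performs $N$ gradient
steps, each on freshly *randomized* SMILES of the batch **and the entire
experience-replay buffer** — SMILES are non-injective, so a score earned by
a molecule is valid for every string that writes it, and the prior
likelihood of each new writing gives a fresh, informative regression
target.

Also included:

* **Baselines** — REINVENT-style updates, Augmented Hill-Climb (top-k
  selection), Best Agent Reminder (best-agent replay at weight α).
* **Diversity machinery** — Bemis–Murcko scaffold buckets (zero reward
  once a bucket of 25 fills) and **Selective Memory Purge**, which removes
  penalized scaffolds from the replay buffer each epoch so augmented
  updates never reinforce dead scaffolds.
* **Scoring** — weighted-geometric-mean multi-parameter objectives: Morgan
  (ECFP-style) Tanimoto similarity, QED drug-likeness, molecular-weight
  gates, and pluggable external-oracle adapters (reverse-sigmoid transforms
  for docking-style minimized quantities); an oracle ledger that charges
  one call per distinct molecule, making duplicates and augmented
  representations free.
* **Metrics** — AUC Top-10 over an oracle budget (step-integrated running
  mean of the 10 best rewards) and MOSES-style internal diversity
  (IntDiv1).
* **Fixture world** — a deterministic combinatorial library (~780
  template×substituent molecules) to train a small prior and run
  rediscovery experiments offline in minutes.

Chemistry (canonicalization, logP/TPSA, SMARTS) runs on OpenBabel through
ChemmineOB; graph-level operations (strict parsing, SMILES randomization,
scaffolds, fingerprints) are implemented in the package. The LSTM policy,
its backpropagation and Adam are plain R matrix code — small enough to
read, fast enough for the fixture scale.

## Worked example

```r
library(augmem)

# drug-likeness of risperidone, the DRD2 reference drug
qed(ref_molecules()[["risperidone"]])
#> [1] 0.6584574   # 0.66 at two decimals

# fixture world: 500-molecule corpus + held-out similarity target
task <- mini_similarity_task()
set.seed(480003)
prior <- train_prior(task$corpus, epochs = 90, lr = 5e-3, batch_size = 32,
                     emb_size = 48, hidden_sizes = 128,
                     augment = TRUE)   # ~4 min CPU; see the vignette

cfg <- default_run_config(task$target, algorithm = "ahc", budget = 3000,
                          seed = 1, batch_size = 32, learning_rate = 2e-3,
                          max_length = 48)
cfg$stop_at_mean_reward <- 0.8
state <- run_experiment(cfg, prior = prior)
first_crossing(state$log, 0.8)
#> [1] 578   # oracle calls until the mean batch reward first reached 0.8
```

`first_crossing()` is the sample-efficiency yardstick used to compare
`augmented_memory` against `reinvent`/`ahc`/`bar` under matched seeds;
`evaluate_run()` reports AUC Top-10 over the budget, IntDiv1 of the best
molecules, and the number of distinct scaffolds found. The methods
vignette documents the fixture-world conditions in detail — including the
honest finding that at this miniature scale the raw-sample baselines
out-race augmented replay, whose advantage depends on representation
generalization that only full-scale priors provide; the mechanism-level
guarantees (one oracle charge per epoch however many augmentation rounds
run, score reuse across representations, purge semantics) are what the
test suite verifies green.

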