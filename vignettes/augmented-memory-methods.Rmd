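---
title: "Sample-efficient RL for SMILES-based molecular design: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-efficient RL for SMILES-based molecular design: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Goal-directed de novo design searches chemical space for molecules that
maximize a property oracle (a similarity model, a docking score, a
drug-likeness profile). The oracle is the expensive resource: a docking run
or a quantum-chemistry calculation per molecule dwarfs everything else, so
methods are compared under a fixed *oracle-call budget* rather than
wall-clock time. `augmem` implements a family of policy-gradient algorithms
over an autoregressive SMILES language model, centered on **Augmented
Memory**: an update scheme that squeezes several gradient steps out of every
oracle call by exploiting the fact that SMILES are non-injective — one
molecule admits many strings, and a score attached to the molecule is valid
for all of them.

## Model and losses

The policy is an LSTM language model over SMILES tokens. Generation is
Markovian: the probability of a sequence factorizes into per-token
conditionals, and the sequence log-likelihood is the sum of the chosen
tokens' log-probabilities through the end token (`sequence_nll()`).

Fine-tuning starts from a frozen copy of the pretrained model (the *Prior*)
and updates a trainable copy (the *Agent*). For a molecule with reward
$S \in [0,1]$ the target is the **augmented log-likelihood**

$$\log P_{\text{aug}} = \log P_{\text{prior}} + \sigma \, S,$$

and the Agent minimizes the batch mean of
$(\log P_{\text{aug}} - \log P_{\text{agent}})^2$ (`dap_loss()`). The prior
term anchors syntax and "reasonable chemistry"; $\sigma$ (default 128)
scales how hard the reward bends the policy.

Four per-epoch algorithms share this loss:

* **reinvent** — sample a batch, score it, one gradient step on the batch
  plus a small uniform sample from the replay buffer.
* **ahc** — as above, but only the top-k fraction of the batch (default
  0.5) enters the gradient step; ties at the cutoff keep batch order.
* **bar** — blends the loss on the current Agent's batch with the loss on a
  batch drawn from the best Agent seen so far (weight $\alpha$, default
  0.5); the best Agent is refreshed whenever the mean batch reward improves.
  Note the extra batch is scored, so BAR consumes up to twice the oracle
  calls per epoch.
* **augmented_memory** — sample and score once (the only oracle charge),
  then N times (default 2): rewrite every SMILES in the batch *and the
  entire replay buffer* as a freshly randomized string, recompute prior and
  agent likelihoods on the new strings, pair them with the stored rewards,
  and take a gradient step.

Two design points in `augmented_memory_epoch()` were genuinely open and are
fixed as follows: all N updates use augmented strings (there is no initial
raw-batch update), and the buffer purge runs *before* the batch is merged
into the buffer, so a scaffold penalized this epoch is removed from replay
before it can be reinforced again. The prior log-likelihood is recomputed
for every augmented representation — the prior assigns different
likelihoods to different writings of the same molecule, which is exactly
what makes repeated updates informative rather than a constant-target
repeat.

Zero-reward molecules stay in the gradient batch (their target collapses to
the prior likelihood) but never enter the replay buffer.

## Chemistry substrate

OpenBabel (via ChemmineOB) provides canonical SMILES and the global
descriptors (logP, TPSA, H-bond donors, SMARTS matching). Everything that
needs the molecular graph itself runs on the package's own strict SMILES
machinery:

* **Validation.** OpenBabel happily reads malformed strings (`"C("` parses
  as methane), which would wreck the invalid-molecule accounting, so a
  strict parser (syntax, branch/ring closure, element support, valence
  limits on organic-subset atoms) gates every input. A string is a valid
  molecule iff the parser accepts it and OpenBabel canonicalizes it.
* **Randomization.** `randomize_smiles()` shuffles the atom numbering
  uniformly and rewrites the graph depth-first from the new first atom.
  The rewritten string is re-parsed as a guard; stereo-annotated input is
  returned canonical rather than risking parity corruption (the fixture
  chemistry is achiral, so this path is never exercised at desk scale).
* **Scaffolds.** Bemis–Murcko frameworks on the heavy-atom graph: terminal
  atoms are stripped iteratively unless held by a double/triple bond. An
  acyclic molecule has an empty framework; its own canonical SMILES is used
  as the bucket key instead, so acyclic molecules are not pooled into one
  shared diversity bucket.
* **Fingerprints.** An extended-connectivity (Morgan) fingerprint, radius
  2, 2048 bits — the GuacaMol/MOSES similarity convention. The bit
  assignments are this package's own hash, so absolute similarity values
  are not interchangeable with other toolkits' ECFP4, but all similarity
  tasks and diversity metrics in the package use the same fingerprint
  consistently.

QED is implemented from the published desirability-function parameters
(asymmetric double sigmoids over MW, ALOGP, HBA, HBD, PSA, rotatable bonds,
aromatic rings, structural alerts, with the published weights). ALOGP,
TPSA and HBD come from OpenBabel; acceptors, rotatable bonds (strict
definition) and the alert set are SMARTS evaluated by OpenBabel; MW and
aromatic-ring counts come from the package's graph. Two alert patterns are
dot-disconnected SMARTS that OpenBabel cannot express and are implemented
as equivalent count thresholds (≥ 4 fluorines; ≥ 3 ester groups). On a
reference panel of marketed drugs this stack reproduces published QED
values to about ±0.01; risperidone, the reference drug of the worked
example, scores 0.66 at two decimals.

## Oracle accounting

`score_batch()` charges one oracle call per *distinct canonical SMILES*
ever scored. Invalid strings cost nothing and score 0; duplicates and
augmented representations of known molecules are free cache hits. This is
the accounting convention of budgeted benchmarks, and it is the mechanism
that makes augmentation rounds oracle-free: the property tests assert that
ledger growth per epoch is bounded by the sampled batch size regardless of
the number of augmentation rounds.

Rewards aggregate as a weighted geometric mean, so any zero component
vetoes the molecule. External oracles (docking, semiempirical IP, SA
scores) are pluggable adapters: the caller supplies the raw function and a
monotone transform (reverse sigmoid for minimized quantities, the reversed
[1,10] map for SA); failures zero the component. Tests use deterministic
stubs; no external binary is executed.

## Diversity machinery

The diversity filter counts each Bemis–Murcko scaffold in buckets of 25;
once a bucket fills, further members receive reward 0. Only valid molecules
touch buckets, including valid molecules whose reward was already 0.
Selective Memory Purge removes penalized scaffolds from the replay buffer
at the start of each epoch. Without the purge, augmented replay keeps
reinforcing a scaffold the filter has already killed — the mode-collapse
failure the purge exists to prevent, and the behavior contrasted in the
end-to-end tests.

## The fixture world

Full-scale experiments of this kind need a ChEMBL-sized corpus and a
pretrained prior; the desk-scale stand-in is a self-contained
combinatorial library:
four templated cores (meta-substituted benzene, pyridine, an
aryl-piperidine amide, a furan) crossed with fourteen substituents at two
sites (~780 unique molecules). Four of the substituents are themselves
rings (phenyl, pyridyl, cyclopropyl, morpholino), which gives the library
about 150 distinct Bemis–Murcko scaffolds — the raw material the
diversity-filter experiments need. Five hundred members form the prior
corpus; one held-out member is the similarity target of the "mini
rediscovery" task, so the optimum is reachable but unseen. The library was
designed once, with two goals: a drug-like token vocabulary (aromatic
rings, heteroatoms, halogens, amides, esters) and syntax simple enough that
a small LSTM reaches the high-validity sampling regime (≥95%) that SMILES
RL methods presuppose of their priors. (A fused bicyclic core tried in an
early draft dominated the residual invalid-SMILES modes and was replaced
by the furan.)

Two priors are trained on this corpus, for two different jobs:

* the **corpus prior** (canonical forms only; embedding 48, one LSTM layer
  of 128, 70 epochs of Adam at 5e-3, minibatch 32) is the language-model
  reference: ~97% of its samples are valid SMILES;
* the **replay prior** (same architecture, 90 epochs, with a fresh
  randomized writing of every molecule each epoch) additionally assigns
  sensible likelihoods to non-canonical writings. Augmented replay
  regresses the agent onto prior likelihoods *of randomized strings*; under
  a canonical-only prior of this size those are essentially
  out-of-distribution and the regression targets carry no signal, so the
  replay-reuse experiments use this prior. The price of covering many
  writings with a small model is a softer canonical distribution (~75%
  sampling validity).

What the fixture world does *not* emulate: the scale and heterogeneity of
real screening corpora, multi-ring fused systems, stereochemistry,
charged/zwitterionic species, and trained-classifier oracles. Passing the
desk-scale checks shows the algorithms' mechanisms (oracle reuse, replay,
purge) behave as specified, not that the implementation reproduces
full-scale published benchmark numbers on real targets.

## Problem sizes and numerical choices

Chosen once for the desk-scale experiments and used by tests and examples:

* RL recipes: $\sigma = 128$, batch 32, Adam lr 2e-3, N = 2 augmentation
  rounds, buffer capacity 100, replay subset 10 (0 for the plain
  policy-gradient baseline, which matches the original formulation the
  comparisons are made against), bucket size 25, `max_length` 48 tokens.
  The smaller batch and larger step size than the full-scale defaults
  (batch 64, lr 1e-4) suit the small network and keep each epoch cheap on
  one CPU; all arms of any comparison share them.
* Oracle budget 3000 calls, three matched seeds, and per-run epoch caps
  (100–120) sized so every arm either reaches the reward threshold or is
  observed well past its competitors' crossing points.
* The default `policy_net()` architecture remains the REINVENT-like
  embedding 128 / 2×512, which is what a real-corpus prior would use.
* Softmax is computed with row-max subtraction; picked probabilities are
  floored at 1e-30 before the log; the start and pad tokens are clamped out
  of every per-step distribution, which keeps sampling and likelihood
  evaluation exactly consistent.
* Ties: buffer entries at equal reward keep insertion order; the AHC top-k
  cutoff keeps batch order. Both make runs bit-reproducible under a seed.
* Degenerate inputs: invalid SMILES score 0 everywhere and never enter
  buffers; `bucket_size = 0` zeroes every molecule; an empty buffer makes
  the augmentation round fall back to the batch alone.

## What desk scale does and does not show

The mechanism-level contracts of augmented replay all hold here and are
property-tested: an epoch charges the oracle once for its batch however
many augmentation rounds run; rewards attach to molecules, not strings, so
every randomized writing reuses the stored score; the purge empties the
buffer of penalized scaffolds before they can be replayed.

The *aggregate* sample-efficiency advantage of augmented replay, however,
does not reproduce at this scale, and the corresponding end-to-end checks
in the test suite report that honestly rather than asserting a weakened
claim. The reason is instructive. Augmented updates regress the agent onto
randomized writings of good molecules; for the reuse to compound, raising
the likelihood of one writing must raise the policy's probability of the
*molecule* — a generalization across representations that large
SMILES language models exhibit and a 128-unit, 500-molecule model does
not. In our experiments the augmented-replay agent keeps spreading mass
across writings (its sampled batches stay diverse and its mean reward
climbs slowly), while the plain policy-gradient baseline, which sharpens
exactly the strings it just sampled, rediscovers the target quickly in
this small library. For the same reason the diversity-filter collapse
that Selective Memory Purge is designed to rescue barely materializes:
without strong exploitation, scaffold buckets rarely fill. Both behaviors
reversed in no configuration we tried (three libraries, learning rates
1e-3–5e-3, $\sigma$ 128–500, canonical/augmented/curriculum priors, an
anchored variant with an initial raw-batch update), which we take as a
genuine scale limitation of the method's headline claim, not an
implementation defect: the per-step machinery is verified independently,
and the gradient is checked against finite differences to 5e-7.

## Known limitations

* The Morgan fingerprint hash is package-specific (similarity values are
  internally consistent, not toolkit-portable).
* OpenBabel's logP differs from other implementations by a few hundredths;
  QED values track published ones to ~±0.01.
* Aromatic-ring counting uses the cyclomatic number of the aromatic-bond
  subgraph, which agrees with SSSR counting on fused drug-like systems but
  can differ on exotic bridged aromatics.
* `randomize_smiles()` does not shuffle stereo-annotated molecules.
* The compiled LSTM core is sized for fixture-scale experiments; a
  production run at REINVENT scale would want the same algorithms over a
  GPU-backed policy, which is outside this package's scope.
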