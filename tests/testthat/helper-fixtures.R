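# Shared fixtures. The fixture prior is expensive (about two minutes of
# training), so it is built lazily once per test run and reused by every
# test that needs a realistic policy.

.fixtures <- new.env(parent = emptyenv())

fixture_task <- function() {
  if (is.null(.fixtures$task)) .fixtures$task <- mini_similarity_task()
  .fixtures$task
}

# realistic prior: trained on the 500-molecule fixture corpus with the
# configuration the bench recipes document (embedding 48, one LSTM layer of
# 128, 70 epochs of Adam at 5e-3 with minibatch 32)
fixture_prior <- function() {
  if (is.null(.fixtures$prior)) {
    task <- fixture_task()
    set.seed(480001L)
    .fixtures$prior <- train_prior(
      task$corpus, epochs = 70L, lr = 5e-3, lr_decay = 1,
      batch_size = 32L, emb_size = 48L, hidden_sizes = 128L
    )
  }
  .fixtures$prior
}

# augmentation-aware prior for the replay-reuse experiments: trained with
# per-epoch randomized-SMILES augmentation so that alternative writings of a
# molecule are in-distribution (a canonical-only prior at this corpus size
# assigns them vanishing likelihood, which starves the augmented-replay
# regression targets); hidden size 96 keeps the experiment epochs fast
fixture_rl_prior <- function() {
  if (is.null(.fixtures$rl_prior)) {
    task <- fixture_task()
    set.seed(480003L)
    .fixtures$rl_prior <- train_prior(
      task$corpus, epochs = 90L, lr = 5e-3, lr_decay = 1,
      batch_size = 32L, emb_size = 48L, hidden_sizes = 128L, augment = TRUE
    )
  }
  .fixtures$rl_prior
}

# tiny prior for cheap structural tests of the epoch machinery (seconds)
cheap_prior <- function() {
  if (is.null(.fixtures$cheap)) {
    task <- fixture_task()
    set.seed(480002L)
    .fixtures$cheap <- train_prior(
      task$corpus[1:60], epochs = 3L, lr = 5e-3,
      batch_size = 32L, emb_size = 16L, hidden_sizes = 32L
    )
  }
  .fixtures$cheap
}

# policy with all-zero parameters: uniform distribution over the usable
# tokens (everything except pad and start)
uniform_policy <- function(corpus) {
  vocab <- build_vocabulary(corpus)
  m <- policy_net(vocab, emb_size = 4L, hidden_sizes = 8L)
  zero <- function(x) { x[] <- 0; x }
  m$params$emb <- zero(m$params$emb)
  m$params$Wo <- zero(m$params$Wo)
  m$params$bo <- zero(m$params$bo)
  for (l in seq_along(m$params$layers)) {
    m$params$layers[[l]]$Wx <- zero(m$params$layers[[l]]$Wx)
    m$params$layers[[l]]$Wh <- zero(m$params$layers[[l]]$Wh)
    m$params$layers[[l]]$b <- zero(m$params$layers[[l]]$b)
  }
  m
}

# scored-molecule rows for buffer/filter tests without touching an oracle
scored_rows <- function(smiles, reward, scaffold = smiles,
                        valid = rep(TRUE, length(smiles))) {
  data.frame(smiles = smiles, canonical_smiles = smiles, valid = valid,
             reward = reward, scaffold = scaffold, stringsAsFactors = FALSE)
}

# constant-valued scoring component
const_component <- function(name, value, weight = 1) {
  scoring_component(name, raw_fn = function(s) value, weight = weight)
}
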