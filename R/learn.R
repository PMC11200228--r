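# Policy-gradient fine-tuning: the augmented-likelihood target, the
# squared-difference loss, and the per-epoch update algorithms
# (REINVENT-style baseline, Augmented Hill-Climb, Best Agent Reminder, and
# Augmented Memory).
#
# The target log-likelihood for a molecule with reward S is
#     logP_aug = logP_prior + sigma * S
# and the Agent is regressed onto it by minimizing the batch mean of
# (logP_aug - logP_agent)^2. Augmented Memory charges the oracle once per
# epoch, then performs N gradient steps, each on freshly randomized SMILES
# of the sampled batch and the entire replay buffer, reusing the stored
# rewards.

#' Augmented log-likelihood target
#'
#' `prior_loglik + sigma * reward`, the linear blend of prior likelihood
#' (which anchors syntax and reasonable chemistry) and the reward.
#'
#' @param prior_loglik numeric vector of prior log-likelihoods.
#' @param reward rewards in `[0, 1]`.
#' @param sigma positive reward-scaling hyperparameter.
#' @return numeric vector.
#' @export
augmented_log_likelihood <- function(prior_loglik, reward, sigma) {
  stopifnot(sigma >= 0, all(reward >= 0 & reward <= 1))
  prior_loglik + sigma * reward
}

#' Squared-difference policy loss
#'
#' Batch mean of `(augmented_loglik - agent_loglik)^2`.
#'
#' @param agent_loglik,augmented_loglik equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
dap_loss <- function(agent_loglik, augmented_loglik) {
  if (length(agent_loglik) != length(augmented_loglik)) {
    stop("length mismatch: ", length(agent_loglik), " vs ",
         length(augmented_loglik))
  }
  mean((augmented_loglik - agent_loglik)^2)
}

#' Reinforcement-learning configuration
#'
#' @param sigma reward scaling in the augmented likelihood.
#' @param batch_size molecules sampled per epoch.
#' @param learning_rate Adam learning rate for agent updates.
#' @param augmentation_rounds N, gradient steps per epoch for Augmented
#'   Memory.
#' @param algorithm one of `"reinvent"`, `"ahc"`, `"bar"`,
#'   `"augmented_memory"`.
#' @param ahc_topk_fraction fraction of the batch kept by AHC.
#' @param bar_alpha weight of the best-agent batch in the BAR loss.
#' @param replay_sample_size replay subset size for the baseline algorithms.
#' @param max_length token cap per sampled sequence.
#' @return list of class `"rl_config"`.
#' @export
rl_config <- function(sigma = 128, batch_size = 64L, learning_rate = 1e-4,
                      augmentation_rounds = 2L, algorithm = "reinvent",
                      ahc_topk_fraction = 0.5, bar_alpha = 0.5,
                      replay_sample_size = 10L, max_length = 256L) {
  algorithm <- match.arg(algorithm,
                         c("reinvent", "ahc", "bar", "augmented_memory"))
  stopifnot(sigma > 0, batch_size >= 1L, learning_rate > 0,
            augmentation_rounds >= 1L,
            ahc_topk_fraction > 0, ahc_topk_fraction <= 1,
            bar_alpha >= 0, bar_alpha <= 1, replay_sample_size >= 0L,
            max_length >= 2L)
  structure(list(sigma = sigma, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 augmentation_rounds = as.integer(augmentation_rounds),
                 algorithm = algorithm,
                 ahc_topk_fraction = ahc_topk_fraction,
                 bar_alpha = bar_alpha,
                 replay_sample_size = as.integer(replay_sample_size),
                 max_length = as.integer(max_length)),
            class = "rl_config")
}

#' Initialize a training state
#'
#' The Agent starts as a copy of the Prior; the Prior itself is frozen and
#' never updated. The state carries the optimizer, the oracle ledger, the
#' replay buffer and the diversity filter, and has reference semantics: the
#' epoch functions mutate it in place.
#'
#' @param prior a trained [policy_net()].
#' @param config an [rl_config()].
#' @param buffer_capacity replay-buffer size.
#' @param bucket_size diversity-filter bucket size.
#' @param use_diversity_filter zero rewards of over-sampled scaffolds.
#' @param use_purge apply Selective Memory Purge each epoch (Augmented
#'   Memory).
#' @return object of class `"rl_state"`.
#' @export
training_state <- function(prior, config = rl_config(),
                           buffer_capacity = 100L, bucket_size = 25L,
                           use_diversity_filter = FALSE, use_purge = FALSE) {
  stopifnot(inherits(prior, "policy_net"), inherits(config, "rl_config"))
  e <- new.env(parent = emptyenv())
  e$prior <- prior
  e$agent <- prior           # R copy-on-modify: agent updates never touch prior
  e$best_agent <- prior
  e$best_mean_reward <- -Inf
  e$config <- config
  e$opt <- .adam_init(prior$params)
  e$epoch <- 0L
  e$ledger <- oracle_ledger()
  e$buffer <- replay_buffer(buffer_capacity)
  e$df <- diversity_filter(bucket_size)
  e$use_df <- isTRUE(use_diversity_filter)
  e$use_purge <- isTRUE(use_purge)
  e$log <- data.frame()
  e$snapshots <- list()
  class(e) <- "rl_state"
  e
}

#' @export
print.rl_state <- function(x, ...) {
  cat("RL state:", x$config$algorithm, "| epoch", x$epoch, "| oracle calls",
      ledger_calls(x$ledger), "| buffer", buffer_size(x$buffer), "\n")
  invisible(x)
}

# encode a string for the agent, falling back to the molecule's canonical
# form when an augmented representation contains out-of-vocabulary tokens
.encode_or_fallback <- function(vocab, smiles, fallback) {
  tryCatch(encode_smiles(smiles, vocab), error = function(e) {
    tryCatch(encode_smiles(fallback, vocab), error = function(e2) NULL)
  })
}

# one gradient step of the squared-difference loss on (smiles, reward) pairs;
# returns the loss value before the step
.dap_step <- function(state, smiles, rewards) {
  cfg <- state$config
  vocab <- state$agent$vocab
  seqs <- vector("list", length(smiles))
  keep <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    sq <- .encode_quiet(smiles[i], vocab)
    if (!is.null(sq)) { seqs[[i]] <- sq; keep[i] <- TRUE }
  }
  if (!any(keep)) return(NA_real_)
  seqs <- seqs[keep]; rewards <- rewards[keep]
  prior_ll <- -.policy_forward(state$prior, seqs)$nll
  aug_ll <- augmented_log_likelihood(prior_ll, rewards, cfg$sigma)
  res <- .policy_dap_grad(state$agent, seqs, aug_ll)
  upd <- .adam_update(state$agent$params, res$grads, state$opt,
                      cfg$learning_rate)
  state$agent$params <- upd$params
  state$opt <- upd$state
  res$loss
}

.log_epoch <- function(state, batch, loss) {
  state$log <- rbind(state$log, data.frame(
    epoch = state$epoch,
    oracle_calls = ledger_calls(state$ledger),
    mean_reward = mean(batch$reward),
    max_reward = if (nrow(batch)) max(batch$reward) else 0,
    frac_valid = mean(batch$valid),
    buffer_size = buffer_size(state$buffer),
    loss = loss
  ))
}

# shared epoch skeleton: sample, score, filter, store
.sample_and_score <- function(state, objective) {
  cfg <- state$config
  s <- sample_batch(state$agent, cfg$batch_size, cfg$max_length)
  batch <- score_batch(objective, s$smiles, state$ledger)
  if (state$use_df) batch <- df_apply(state$df, batch)
  batch
}

#' One epoch of the REINVENT-style baseline
#'
#' Sample, score, update the replay buffer, then one gradient step on the
#' batch plus a uniformly drawn replay subset.
#'
#' @param state an [training_state()] object; mutated in place.
#' @param objective an [objective_function()].
#' @return the state, invisibly.
#' @export
reinvent_epoch <- function(state, objective) {
  batch <- .sample_and_score(state, objective)
  buffer_update(state$buffer, batch)
  rep_df <- buffer_sample(state$buffer, state$config$replay_sample_size)
  smiles <- c(batch$smiles, rep_df$canonical_smiles)
  rewards <- c(batch$reward, rep_df$reward)
  loss <- .dap_step(state, smiles, rewards)
  state$epoch <- state$epoch + 1L
  .log_epoch(state, batch, loss)
  invisible(state)
}

#' One epoch of Augmented Hill-Climb
#'
#' As the baseline, but the gradient step uses only the top-k fraction of
#' the batch by reward (ties broken by batch order), plus the replay subset.
#'
#' @inheritParams reinvent_epoch
#' @return the state, invisibly.
#' @export
ahc_epoch <- function(state, objective) {
  cfg <- state$config
  batch <- .sample_and_score(state, objective)
  buffer_update(state$buffer, batch)
  k <- ceiling(nrow(batch) * cfg$ahc_topk_fraction)
  top <- order(-batch$reward)[seq_len(k)]   # stable: ties keep batch order
  sel <- batch[sort(top), , drop = FALSE]
  rep_df <- buffer_sample(state$buffer, cfg$replay_sample_size)
  smiles <- c(sel$smiles, rep_df$canonical_smiles)
  rewards <- c(sel$reward, rep_df$reward)
  loss <- .dap_step(state, smiles, rewards)
  state$epoch <- state$epoch + 1L
  .log_epoch(state, batch, loss)
  invisible(state)
}

#' One epoch of Best Agent Reminder
#'
#' Blends the squared-difference loss on the current agent's batch with the
#' loss on a batch sampled from the best agent seen so far (weight `alpha`);
#' the best agent is refreshed whenever the current mean batch reward beats
#' the best mean recorded.
#'
#' @inheritParams reinvent_epoch
#' @return the state, invisibly.
#' @export
bar_epoch <- function(state, objective) {
  cfg <- state$config
  batch <- .sample_and_score(state, objective)
  buffer_update(state$buffer, batch)
  best_s <- sample_batch(state$best_agent, cfg$batch_size, cfg$max_length)
  best_batch <- score_batch(objective, best_s$smiles, state$ledger)
  if (state$use_df) best_batch <- df_apply(state$df, best_batch)

  vocab <- state$agent$vocab
  enc <- function(df_rows) {
    seqs <- list(); rew <- numeric(0)
    for (i in seq_len(nrow(df_rows))) {
      sq <- tryCatch(encode_smiles(df_rows$smiles[i], vocab),
                     error = function(e) NULL)
      if (!is.null(sq)) { seqs <- c(seqs, list(sq)); rew <- c(rew, df_rows$reward[i]) }
    }
    list(seqs = seqs, rew = rew)
  }
  cur <- enc(batch); bst <- enc(best_batch)
  loss <- NA_real_
  if (length(cur$seqs) + length(bst$seqs) > 0L) {
    all_seqs <- c(cur$seqs, bst$seqs)
    prior_ll <- -.policy_forward(state$prior, all_seqs)$nll
    agent_ll <- -.policy_forward(state$agent, all_seqs)$nll
    aug_ll <- augmented_log_likelihood(prior_ll, c(cur$rew, bst$rew),
                                       cfg$sigma)
    d <- aug_ll - agent_ll
    nc <- length(cur$seqs); nb <- length(bst$seqs)
    loss <- (if (nc) (1 - cfg$bar_alpha) * mean(d[seq_len(nc)]^2) else 0) +
      (if (nb) cfg$bar_alpha * mean(d[nc + seq_len(nb)]^2) else 0)
    w <- numeric(nc + nb)
    if (nc) w[seq_len(nc)] <- -(1 - cfg$bar_alpha) * 2 / nc * d[seq_len(nc)]
    if (nb) w[nc + seq_len(nb)] <- -cfg$bar_alpha * 2 / nb * d[nc + seq_len(nb)]
    gr <- .policy_grad(state$agent, all_seqs, w)
    upd <- .adam_update(state$agent$params, gr, state$opt, cfg$learning_rate)
    state$agent$params <- upd$params
    state$opt <- upd$state
  }
  mr <- mean(batch$reward)
  if (mr > state$best_mean_reward) {
    state$best_mean_reward <- mr
    state$best_agent <- state$agent
  }
  state$epoch <- state$epoch + 1L
  .log_epoch(state, batch, loss)
  invisible(state)
}

#' One epoch of Augmented Memory
#'
#' (1) sample a batch; (2) score it -- the only oracle charge of the epoch;
#' (3) apply the diversity filter, purge the buffer of penalized scaffolds,
#' and merge the batch into the buffer; (4) N times: randomize every SMILES
#' in the batch and in the entire buffer, recompute prior and agent
#' log-likelihoods on the augmented strings, pair them with the stored
#' rewards, and take one gradient step. Exactly N gradient steps per epoch,
#' zero additional oracle calls.
#'
#' @inheritParams reinvent_epoch
#' @return the state, invisibly.
#' @export
augmented_memory_epoch <- function(state, objective) {
  cfg <- state$config
  batch <- .sample_and_score(state, objective)
  if (state$use_purge) selective_memory_purge(state$buffer, state$df)
  buffer_update(state$buffer, batch)
  loss <- NA_real_
  buf <- buffer_entries(state$buffer)
  for (round in seq_len(cfg$augmentation_rounds)) {
    aug_smiles <- character(nrow(batch))
    for (i in seq_len(nrow(batch))) {
      aug_smiles[i] <- if (batch$valid[i]) {
        randomize_smiles(batch$canonical_smiles[i])
      } else batch$smiles[i]          # invalid strings stay as sampled
    }
    buf_aug <- if (nrow(buf) > 0L) {
      vapply(buf$canonical_smiles, randomize_smiles, "", USE.NAMES = FALSE)
    } else character(0)
    smiles <- c(aug_smiles, buf_aug)
    rewards <- c(batch$reward, buf$reward)
    loss <- .dap_step(state, smiles, rewards)
  }
  state$epoch <- state$epoch + 1L
  .log_epoch(state, batch, loss)
  invisible(state)
}

#' Run one epoch of the configured algorithm
#'
#' @inheritParams reinvent_epoch
#' @return the state, invisibly.
#' @export
run_epoch <- function(state, objective) {
  fn <- switch(state$config$algorithm,
               reinvent = reinvent_epoch,
               ahc = ahc_epoch,
               bar = bar_epoch,
               augmented_memory = augmented_memory_epoch)
  fn(state, objective)
}

#' Negative log-likelihood trace of a target molecule
#'
#' `sequence_nll` of the canonical target under each agent snapshot;
#' monitors how strongly the policy concentrates on (for instance) the
#' similarity target over training.
#'
#' @param agent_snapshots list of [policy_net()] objects.
#' @param target target SMILES.
#' @return numeric vector, one NLL per snapshot.
#' @export
nll_trace <- function(agent_snapshots, target) {
  if (length(agent_snapshots) == 0L) return(numeric(0))
  can <- canonicalize(target)
  if (is.na(can)) stop("invalid target SMILES")
  vapply(agent_snapshots, function(m) sequence_nll(m, can), 1)
}
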