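# Run configuration, fixture corpus generation and the end-to-end
# experiment driver.
#
# The fixture corpus is a small combinatorial library (aromatic cores x
# substituents) that stands in for the large public corpora a production
# prior would be trained on: it is big enough to train a prior that emits
# mostly valid, in-space SMILES, and small enough to train in minutes on one
# CPU. The mini similarity task holds one library member out of the corpus
# and rewards Tanimoto similarity to it -- a dense-reward rediscovery task.

#' Fixture-corpus specification
#'
#' Templates are SMILES with `{A}` and `{B}` substituent sites; the
#' generator enumerates all template x fragment x fragment attachments,
#' canonicalizes, deduplicates, shuffles deterministically and truncates.
#'
#' @param templates character vector of templated SMILES.
#' @param substituents character vector of attachable SMILES fragments.
#' @param n_molecules corpus size to generate.
#' @param seed RNG seed for the deterministic shuffle.
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(templates = NULL, substituents = NULL,
                         n_molecules = 500L, seed = 20260101L) {
  if (is.null(templates)) {
    templates <- c(
      "c1cc({A})cc({B})c1",                  # benzene, meta substitution
      "c1nc({A})cc({B})c1",                  # pyridine
      "O=C({A})N1CCC(CC1)c1ccc({B})cc1",     # aryl-piperidine amide
      "c1oc({A})cc1{B}"                      # furan
    )
  }
  if (is.null(substituents)) {
    # a mix of acyclic groups and ring substituents; the rings multiply the
    # Bemis-Murcko scaffold count of the library (~150 scaffolds in a
    # 500-molecule corpus), which the diversity-filter experiments rely on.
    # Ring substituents use closure digit 2 so that textual attachment into
    # the digit-1 templates stays well-formed.
    substituents <- c("C", "CC", "O", "OC", "N", "F", "Cl", "C#N",
                      "C(=O)O", "C(=O)OC",
                      "c2ccccc2", "c2ccncc2", "C2CC2", "N2CCOCC2")
  }
  structure(list(templates = templates, substituents = substituents,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate the fixture corpus
#'
#' @param spec a [fixture_spec()].
#' @return character vector of `n_molecules` unique canonical SMILES.
#' @export
generate_fixture_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  combos <- character(0)
  for (tpl in spec$templates) {
    has_a <- grepl("{A}", tpl, fixed = TRUE)
    has_b <- grepl("{B}", tpl, fixed = TRUE)
    if (has_a && has_b) {
      for (a in spec$substituents) {
        for (b in spec$substituents) {
          combos <- c(combos,
                      sub("{B}", b, sub("{A}", a, tpl, fixed = TRUE),
                          fixed = TRUE))
        }
      }
    } else if (has_a) {
      for (a in spec$substituents) {
        combos <- c(combos, sub("{A}", a, tpl, fixed = TRUE))
      }
    } else {
      combos <- c(combos, tpl)
    }
  }
  cans <- canonicalize(combos)
  cans <- unique(cans[!is.na(cans)])
  if (length(cans) < spec$n_molecules) {
    stop("combinatorial space too small: ", length(cans), " unique valid ",
         "molecules for n_molecules = ", spec$n_molecules)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  sample(cans, spec$n_molecules)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Held-out similarity target plus prior corpus
#'
#' Generates `n_molecules + 1` fixture molecules; the last is the target and
#' is excluded from the corpus, mirroring a rediscovery experiment in which
#' the optimum is reachable but unseen.
#'
#' @param spec a [fixture_spec()].
#' @return list with `corpus` and `target`.
#' @export
mini_similarity_task <- function(spec = fixture_spec()) {
  spec2 <- spec
  spec2$n_molecules <- spec$n_molecules + 1L
  mols <- generate_fixture_corpus(spec2)
  list(corpus = mols[seq_len(spec$n_molecules)],
       target = mols[spec$n_molecules + 1L])
}

# ---- run configuration -----------------------------------------------------

.build_objective_from_config <- function(task) {
  comps <- list()
  for (c in task$components) {
    w <- if (is.null(c$weight)) 1 else c$weight
    comp <- switch(
      c$type,
      similarity = tanimoto_similarity_component(c$reference, weight = w),
      qed = qed_component(weight = w),
      mw_threshold = mw_threshold_component(
        limit = if (is.null(c$limit)) 500 else c$limit, weight = w),
      constant = {
        val <- c$value
        scoring_component(if (is.null(c$name)) "constant" else c$name,
                          raw_fn = function(s) val, weight = w)
      },
      stop("unknown component type '", c$type, "' in task.components")
    )
    comps <- c(comps, list(comp))
  }
  objective_function(comps)
}

.validate_config <- function(config) {
  need <- function(field, test, what) {
    v <- config[[field]]
    if (is.null(v) || !test(v)) stop("config$", field, ": ", what)
    v
  }
  need("task", is.list, "task definition required")
  if (is.null(config$task$components) || !length(config$task$components)) {
    stop("config$task$components: at least one scoring component required")
  }
  need("budget", function(x) is.numeric(x) && x > 0, "positive oracle budget")
  need("seed", is.numeric, "integer seed required")
  invisible(config)
}

#' Default run configuration for the fixture experiments
#'
#' @param target similarity-target SMILES.
#' @param algorithm algorithm name, see [rl_config()].
#' @param budget oracle-call budget.
#' @param seed run seed (drives sampling, augmentation and replay draws).
#' @param ... overrides merged into the `rl` block.
#' @return config list consumable by [run_experiment()].
#' @export
default_run_config <- function(target, algorithm = "augmented_memory",
                               budget = 3000L, seed = 1L, ...) {
  rl <- list(sigma = 128, batch_size = 64L, learning_rate = 1e-3,
             augmentation_rounds = 2L, ahc_topk_fraction = 0.5,
             bar_alpha = 0.5, replay_sample_size = 10L, max_length = 96L)
  over <- list(...)
  rl[names(over)] <- over
  list(
    task = list(components = list(
      list(type = "similarity", reference = target, weight = 1))),
    algorithm = algorithm,
    rl = rl,
    budget = as.integer(budget),
    seed = as.integer(seed),
    buffer_capacity = 100L,
    diversity_filter = list(enabled = FALSE, bucket_size = 25L),
    selective_purge = FALSE,
    checkpoint_every = 0L,
    stop_at_mean_reward = NULL,
    output_dir = NULL
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config config list.
#' @return `read_run_config()` returns the config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---- experiment driver -----------------------------------------------------

#' Run a goal-directed generation experiment
#'
#' Executes epochs of the configured algorithm until the next epoch could
#' exceed the oracle budget (or an optional reward threshold is reached),
#' then returns the final training state. Fully reproducible under
#' `(config, seed)`. When `config$output_dir` is set, writes `config.yaml`,
#' a per-epoch `log.csv`, the per-epoch sampled molecules to `samples.csv`,
#' buffer snapshots to `buffer.csv`, and agent checkpoints every
#' `checkpoint_every` epochs.
#'
#' @param config config list (see [default_run_config()]) or a YAML path.
#' @param prior a trained [policy_net()]; when `NULL`, a prior is trained
#'   from `config$prior_training` (fields `corpus` -- SMILES vector or .smi
#'   path -- plus [train_prior()] arguments).
#' @return the final `"rl_state"` (invisible).
#' @export
run_experiment <- function(config, prior = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  .validate_config(config)
  set.seed(config$seed %% .Machine$integer.max)

  if (is.null(prior)) {
    pt <- config$prior_training
    if (is.null(pt)) stop("no prior given and no config$prior_training block")
    corpus <- if (is.character(pt$corpus) && length(pt$corpus) == 1L &&
                  file.exists(pt$corpus)) read_smiles(pt$corpus) else pt$corpus
    prior <- train_prior(
      corpus,
      epochs = if (is.null(pt$epochs)) 10L else pt$epochs,
      lr = if (is.null(pt$lr)) 5e-3 else pt$lr,
      emb_size = if (is.null(pt$emb_size)) 128L else pt$emb_size,
      hidden_sizes = if (is.null(pt$hidden_sizes)) c(512L, 512L)
                     else unlist(pt$hidden_sizes)
    )
  }

  rl <- config$rl
  if (is.null(rl)) rl <- list()
  cfg <- rl_config(
    sigma = if (is.null(rl$sigma)) 128 else rl$sigma,
    batch_size = if (is.null(rl$batch_size)) 64L else rl$batch_size,
    learning_rate = if (is.null(rl$learning_rate)) 1e-4 else rl$learning_rate,
    augmentation_rounds = if (is.null(rl$augmentation_rounds)) 2L
                          else rl$augmentation_rounds,
    algorithm = config$algorithm,
    ahc_topk_fraction = if (is.null(rl$ahc_topk_fraction)) 0.5
                        else rl$ahc_topk_fraction,
    bar_alpha = if (is.null(rl$bar_alpha)) 0.5 else rl$bar_alpha,
    replay_sample_size = if (is.null(rl$replay_sample_size)) 10L
                         else rl$replay_sample_size,
    max_length = if (is.null(rl$max_length)) 256L else rl$max_length
  )
  dfc <- config$diversity_filter
  state <- training_state(
    prior, cfg,
    buffer_capacity = if (is.null(config$buffer_capacity)) 100L
                      else config$buffer_capacity,
    bucket_size = if (is.null(dfc$bucket_size)) 25L else dfc$bucket_size,
    use_diversity_filter = isTRUE(dfc$enabled),
    use_purge = isTRUE(config$selective_purge)
  )
  objective <- .build_objective_from_config(config$task)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }

  per_epoch <- cfg$batch_size * (if (cfg$algorithm == "bar") 2L else 1L)
  max_epochs <- if (is.null(config$max_epochs)) {
    as.integer(ceiling(config$budget / cfg$batch_size) * 4L)
  } else config$max_epochs
  ckpt_every <- if (is.null(config$checkpoint_every)) 0L
                else config$checkpoint_every

  while (state$epoch < max_epochs &&
         ledger_calls(state$ledger) + per_epoch <= config$budget) {
    run_epoch(state, objective)
    last <- state$log[nrow(state$log), ]
    if (!is.null(out_dir)) {
      n <- nrow(state$log)
      utils::write.csv(state$log, file.path(out_dir, "log.csv"),
                       row.names = FALSE)
      ent <- buffer_entries(state$buffer)
      if (nrow(ent)) ent$epoch <- state$epoch
      utils::write.table(
        ent, file.path(out_dir, "buffer.csv"), sep = ",",
        row.names = FALSE, col.names = state$epoch == 1L,
        append = state$epoch > 1L)
      if (ckpt_every > 0L && state$epoch %% ckpt_every == 0L) {
        save_policy(state$agent, file.path(
          out_dir, sprintf("agent_epoch%04d.rds", state$epoch)))
      }
    }
    if (!is.null(config$stop_at_mean_reward) &&
        last$mean_reward >= config$stop_at_mean_reward) break
  }
  if (!is.null(out_dir)) {
    utils::write.csv(ledger_history(state$ledger),
                     file.path(out_dir, "samples.csv"), row.names = FALSE)
    save_policy(state$agent, file.path(out_dir, "agent_final.rds"))
  }
  invisible(state)
}

#' Oracle calls needed to first reach a mean batch reward
#'
#' @param log the per-epoch log of an `"rl_state"`.
#' @param threshold mean-reward threshold.
#' @return oracle-call count at first crossing, or `Inf` if never reached.
#' @export
first_crossing <- function(log, threshold) {
  hit <- which(log$mean_reward >= threshold)
  if (length(hit) == 0L) return(Inf)
  log$oracle_calls[hit[1L]]
}

#' Summarize a finished run
#'
#' @param state an `"rl_state"` returned by [run_experiment()].
#' @param budget budget used for AUC normalization (defaults to calls made).
#' @param top_n molecule count cap for the diversity metric.
#' @return list with `auc_top10`, `intdiv1`, `n_distinct_scaffolds`,
#'   `oracle_calls`, `best_reward`.
#' @export
evaluate_run <- function(state, budget = NULL, top_n = 200L) {
  hist <- ledger_history(state$ledger)
  if (is.null(budget)) budget <- max(nrow(hist), 1L)
  top <- hist[order(-hist$reward), , drop = FALSE]
  top <- top[seq_len(min(top_n, nrow(top))), , drop = FALSE]
  scaffs <- hist$scaffold[hist$reward > 0]
  list(
    auc_top10 = auc_topk(hist, k = 10L, budget = budget),
    intdiv1 = if (nrow(top)) intdiv1(top$canonical_smiles) else NA_real_,
    n_distinct_scaffolds = length(unique(scaffs)),
    oracle_calls = ledger_calls(state$ledger),
    best_reward = if (nrow(hist)) max(hist$reward) else 0
  )
}
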