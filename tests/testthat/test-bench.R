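# Fixture generation, run configuration and the experiment driver.

test_that("fixture corpus generation is deterministic and combinatorial", {
  # one template without sites yields exactly itself
  sp1 <- fixture_spec(templates = "c1ccccc1", substituents = character(0),
                      n_molecules = 1L)
  expect_identical(generate_fixture_corpus(sp1), canonicalize("c1ccccc1"))

  sp <- fixture_spec(n_molecules = 120L)
  c1 <- generate_fixture_corpus(sp)
  c2 <- generate_fixture_corpus(sp)
  expect_identical(c1, c2)
  expect_length(c1, 120L)
  expect_identical(anyDuplicated(c1), 0L)
  expect_true(all(is_valid_smiles(c1)))

  # demanding more molecules than the space holds is an error
  sp_small <- fixture_spec(templates = "c1cc({A})ccc1",
                           substituents = c("C", "N"), n_molecules = 10L)
  expect_error(generate_fixture_corpus(sp_small), "too small")
})

test_that("the held-out similarity target is excluded from the corpus", {
  task <- fixture_task()
  expect_length(task$corpus, 500L)
  expect_false(task$target %in% task$corpus)
  expect_true(is_valid_smiles(task$target))
})

test_that("config validation names the offending field", {
  expect_error(run_experiment(list(budget = 10)), "task")
  cfg <- default_run_config("CCO")
  cfg$budget <- -1
  expect_error(run_experiment(cfg, prior = cheap_prior()), "budget")
  cfg2 <- default_run_config("CCO")
  cfg2$task$components[[1]]$type <- "warp_drive"
  expect_error(run_experiment(cfg2, prior = cheap_prior()), "warp_drive")
})

test_that("run config round-trips through yaml", {
  cfg <- default_run_config("CCO", algorithm = "ahc", budget = 99L, seed = 3L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, p)
  cfg2 <- read_run_config(p)
  expect_equal(cfg2$algorithm, "ahc")
  expect_equal(cfg2$budget, 99L)
  expect_equal(cfg2$rl$sigma, cfg$rl$sigma)
})

test_that("the oracle budget is never exceeded", {
  prior <- cheap_prior()
  cfg <- default_run_config(fixture_task()$target, algorithm = "reinvent",
                            budget = 128L, seed = 9L,
                            batch_size = 64L, max_length = 60L)
  st <- run_experiment(cfg, prior = prior)
  expect_lte(ledger_calls(st$ledger), 128L)
  # at most two scoring epochs can be charged with batch 64
  expect_lte(nrow(st$log), 8L)          # epoch cap guards the loop
  expect_lte(sum(st$log$oracle_calls == ledger_calls(st$ledger)), nrow(st$log))
})

test_that("runs are byte-identical under a fixed config and seed", {
  prior <- cheap_prior()
  cfg <- default_run_config(fixture_task()$target,
                            algorithm = "augmented_memory",
                            budget = 96L, seed = 17L,
                            batch_size = 32L, max_length = 60L)
  st1 <- run_experiment(cfg, prior = prior)
  st2 <- run_experiment(cfg, prior = prior)
  expect_identical(ledger_history(st1$ledger), ledger_history(st2$ledger))
  expect_identical(st1$log, st2$log)
  expect_identical(st1$agent$params, st2$agent$params)
})

test_that("run artifacts land in the output directory", {
  prior <- cheap_prior()
  out <- withr::local_tempdir()
  cfg <- default_run_config(fixture_task()$target, algorithm = "reinvent",
                            budget = 64L, seed = 23L,
                            batch_size = 32L, max_length = 60L)
  cfg$output_dir <- out
  cfg$checkpoint_every <- 1L
  st <- run_experiment(cfg, prior = prior)
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "log.csv")))
  expect_true(file.exists(file.path(out, "samples.csv")))
  expect_true(file.exists(file.path(out, "agent_final.rds")))
  log <- utils::read.csv(file.path(out, "log.csv"))
  expect_identical(nrow(log), nrow(st$log))
  # final checkpoint reloads to the same policy
  m <- load_policy(file.path(out, "agent_final.rds"))
  expect_identical(m$params, st$agent$params)
})

test_that("evaluate_run reports the budgeted metrics", {
  prior <- cheap_prior()
  cfg <- default_run_config(fixture_task()$target, algorithm = "reinvent",
                            budget = 64L, seed = 29L,
                            batch_size = 32L, max_length = 60L)
  st <- run_experiment(cfg, prior = prior)
  ev <- evaluate_run(st, budget = 64L)
  expect_true(ev$auc_top10 >= 0 && ev$auc_top10 <= 1)
  expect_true(is.na(ev$intdiv1) || (ev$intdiv1 >= 0 && ev$intdiv1 < 1))
  expect_gte(ev$n_distinct_scaffolds, 0L)
  expect_lte(ev$oracle_calls, 64L)
})

test_that("first_crossing finds the oracle cost of a reward threshold", {
  log <- data.frame(epoch = 1:4, oracle_calls = c(60, 120, 180, 240),
                    mean_reward = c(0.1, 0.5, 0.85, 0.9))
  expect_equal(first_crossing(log, 0.8), 180)
  expect_equal(first_crossing(log, 0.95), Inf)
})
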