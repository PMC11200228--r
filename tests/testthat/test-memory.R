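# Replay buffer, diversity filter, Selective Memory Purge.

test_that("buffer keeps the top-k unique molecules, reward-sorted", {
  buf <- replay_buffer(capacity = 3L)
  buffer_update(buf, scored_rows(c("A", "B"), c(0.9, 0.1)))
  buffer_update(buf, scored_rows(c("C", "D"), c(0.5, 0.7)))
  expect_identical(buffer_entries(buf)$canonical_smiles, c("A", "D", "C"))
  expect_equal(buffer_entries(buf)$reward, c(0.9, 0.7, 0.5))
  expect_lte(buffer_size(buf), 3L)

  # duplicate at higher reward upgrades the single entry
  buf2 <- replay_buffer(10L)
  buffer_update(buf2, scored_rows("X", 0.4))
  buffer_update(buf2, scored_rows("X", 0.6))
  expect_identical(buffer_size(buf2), 1L)
  expect_equal(buffer_entries(buf2)$reward, 0.6)
  # ... and a lower reward never downgrades it
  buffer_update(buf2, scored_rows("X", 0.2))
  expect_equal(buffer_entries(buf2)$reward, 0.6)
})

test_that("invalid and zero-reward molecules never enter the buffer", {
  buf <- replay_buffer(5L)
  buffer_update(buf, scored_rows(c("A", "B"), c(0, 0.5),
                                 valid = c(TRUE, FALSE)))
  expect_identical(buffer_size(buf), 0L)
  batch <- scored_rows("bad", 0.9, valid = FALSE)
  buffer_update(buf, batch)
  expect_identical(buffer_size(buf), 0L)
})

test_that("ties at equal reward preserve insertion order", {
  buf <- replay_buffer(5L)
  buffer_update(buf, scored_rows(c("A", "B"), c(0.5, 0.5)))
  buffer_update(buf, scored_rows("C", 0.5))
  expect_identical(buffer_entries(buf)$canonical_smiles, c("A", "B", "C"))
})

test_that("buffer sampling is uniform-without-replacement and seeded", {
  buf <- replay_buffer(10L)
  buffer_update(buf, scored_rows(LETTERS[1:6], seq(0.9, 0.4, by = -0.1)))
  expect_identical(nrow(buffer_sample(buf, 0L)), 0L)
  all6 <- buffer_sample(buf, 99L)
  expect_setequal(all6$canonical_smiles, LETTERS[1:6])
  set.seed(21); s1 <- buffer_sample(buf, 3L)
  set.seed(21); s2 <- buffer_sample(buf, 3L)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1$canonical_smiles), 0L)
})

test_that("buffer augmentation rewrites molecules without oracle calls", {
  buf <- replay_buffer(10L)
  mols <- canonicalize(c("Cc1ccccc1", "CCOC(=O)c1ccncc1", "O=C(N)C1CCNCC1"))
  buffer_update(buf, scored_rows(mols, c(0.9, 0.8, 0.7)))
  led <- oracle_ledger()
  set.seed(33)
  aug <- buffer_augment(buf)
  expect_identical(nrow(aug), 3L)
  expect_identical(canonicalize(aug$smiles), aug$canonical_smiles)
  expect_equal(aug$reward, c(0.9, 0.8, 0.7))
  expect_identical(ledger_calls(led), 0L)  # oracle-free contract
})

test_that("diversity filter zeroes a scaffold once its bucket fills", {
  df <- diversity_filter(bucket_size = 25L)
  batch <- scored_rows(sprintf("m%02d", 1:26), rep(0.8, 26),
                       scaffold = rep("S", 26))
  out <- df_apply(df, batch)
  expect_equal(out$reward[1:25], rep(0.8, 25))
  expect_equal(out$reward[26], 0)
  expect_equal(out$reward_oracle[26], 0.8)  # oracle value is retained
  expect_identical(unname(df_counts(df)[["S"]]), 26L)

  # distinct scaffolds never affect each other
  out2 <- df_apply(df, scored_rows("x", 0.5, scaffold = "T"))
  expect_equal(out2$reward, 0.5)

  # degenerate bucket size zero: everything is penalized
  df0 <- diversity_filter(0L)
  out3 <- df_apply(df0, scored_rows(c("a", "b"), c(0.3, 0.9)))
  expect_equal(out3$reward, c(0, 0))
})

test_that("bucket counts are conserved over valid molecules only", {
  df <- diversity_filter(5L)
  b1 <- scored_rows(c("a", "b", "c"), c(0.1, 0.2, 0.3),
                    scaffold = c("S", "S", "T"))
  b2 <- scored_rows(c("d", "e"), c(0.4, 0), valid = c(TRUE, FALSE),
                    scaffold = c("T", "T"))
  df_apply(df, b1); df_apply(df, b2)
  expect_identical(sum(df_counts(df)), 4L)  # 4 valid molecules processed
})

test_that("selective memory purge removes exactly the penalized scaffolds", {
  df <- diversity_filter(2L)
  df_apply(df, scored_rows(c("a1", "a2"), c(0.5, 0.6),
                           scaffold = c("A", "A")))  # A now full
  buf <- replay_buffer(10L)
  buffer_update(buf, scored_rows(c("a1", "b1", "a2", "b2"),
                                 c(0.9, 0.8, 0.7, 0.6),
                                 scaffold = c("A", "B", "A", "B")))
  selective_memory_purge(buf, df)
  ent <- buffer_entries(buf)
  expect_identical(ent$canonical_smiles, c("b1", "b2"))
  expect_false(any(ent$scaffold %in% df_penalized(df)))

  # no penalized scaffolds -> unchanged
  df2 <- diversity_filter(100L)
  before <- buffer_entries(buf)
  selective_memory_purge(buf, df2)
  expect_identical(buffer_entries(buf), before)

  # all penalized -> empty buffer
  df3 <- diversity_filter(1L)
  df_apply(df3, scored_rows("b", 0.5, scaffold = "B"))
  selective_memory_purge(buf, df3)
  expect_identical(buffer_size(buf), 0L)
})
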