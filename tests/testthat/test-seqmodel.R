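# Vocabulary, tokenizer, and the LSTM policy.

test_that("tokenizer respects multi-character lexical units", {
  expect_identical(smiles_tokens("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(smiles_tokens("ClCCl"), c("Cl", "C", "Cl"))
  expect_identical(smiles_tokens("C[nH]1cc1%12"),
                   c("C", "[nH]", "1", "c", "c", "1", "%12"))
})

test_that("encode/decode round-trips and unknown tokens are a named error", {
  vocab <- build_vocabulary(c("CCO", "c1ccccc1", "ClC"))
  for (s in c("CCO", "c1ccccc1", "ClCCl", "OCC")) {
    ids <- encode_smiles(s, vocab)
    expect_identical(tail(ids, 1L), vocab$end)
    expect_identical(decode_smiles(ids, vocab), s)
  }
  expect_error(encode_smiles("CBr", vocab), "Br")
  # 8 tokens plus terminating end token
  expect_length(encode_smiles("c1ccccc1", vocab), 9L)
  expect_length(encode_smiles("ClCCl", vocab), 4L)
})

test_that("uniform policy gives the closed-form NLL L*log(V)", {
  # corpus tokens C,N,O,S,F,P,I,B,= plus end -> 10 usable symbols
  m <- uniform_policy("123456789")
  expect_length(m$vocab$tokens, 12L)  # 9 digits + pad + start + end
  # 4 tokens + end = 5 sampling steps, each uniform over 10
  expect_equal(sequence_nll(m, "1111"), 5 * log(10), tolerance = 1e-9)
  expect_equal(sequence_nll(m, "2345"), 5 * log(10), tolerance = 1e-9)
})

test_that("per-step distributions are normalized", {
  m <- cheap_prior()
  seqs <- lapply(c("CCO", "c1cc(C)cc(O)c1"), encode_smiles, vocab = m$vocab)
  fw <- augmem:::.policy_forward(m, seqs, keep_cache = TRUE)
  for (P in fw$probs) {
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("a near-deterministic policy emits max-length runs at near-zero NLL", {
  m <- uniform_policy(c("CNO"))
  # force one token's logit up: probability ~1 each step, never terminates
  cidx <- m$vocab$index[["C"]]
  m$params$bo[cidx] <- 50
  set.seed(2)
  s <- sample_batch(m, batch_size = 4L, max_length = 15L)
  expect_true(all(vapply(s$tokens, length, 1L) == 15L))
  expect_true(all(s$smiles == strrep("C", 15L)))
  expect_true(all(s$nll < 1e-6))
})

test_that("sampling is seed-deterministic and NLL-consistent", {
  m <- cheap_prior()
  set.seed(31); s1 <- sample_batch(m, 8L, 40L)
  set.seed(31); s2 <- sample_batch(m, 8L, 40L)
  expect_identical(s1, s2)
  # sequences that terminated with the end token re-score identically
  ended <- vapply(s1$tokens, function(tk) tail(tk, 1L) == m$vocab$end, TRUE)
  if (any(ended)) {
    re <- sequence_nll(m, s1$smiles[ended])
    expect_equal(re, s1$nll[ended], tolerance = 1e-5)
  }
})

test_that("maximum-likelihood training reduces corpus NLL deterministically", {
  corpus <- fixture_task()$corpus[1:40]
  set.seed(9)
  m1 <- train_prior(corpus, epochs = 2L, lr = 5e-3, batch_size = 20L,
                    emb_size = 12L, hidden_sizes = 24L)
  h <- attr(m1, "nll_history")
  expect_lt(tail(h, 1L), h[1L])

  set.seed(9)
  m2 <- train_prior(corpus, epochs = 2L, lr = 5e-3, batch_size = 20L,
                    emb_size = 12L, hidden_sizes = 24L)
  expect_identical(m1$params, m2$params)

  expect_error(train_prior(character(0)), "length")
})

test_that("a one-molecule corpus is memorized", {
  set.seed(12)
  m <- train_prior(rep("CCO", 16L), epochs = 200L, lr = 1e-2, lr_decay = 1,
                   batch_size = 16L, emb_size = 8L, hidden_sizes = 24L)
  expect_lt(sequence_nll(m, "CCO"), 0.1)
  h <- attr(m, "nll_history")
  expect_lt(h[length(h)], h[1] / 10)  # NLL approaches zero with epochs
})

test_that("checkpoints round-trip through the container format", {
  m <- cheap_prior()
  p <- withr::local_tempfile(fileext = ".rds")
  save_policy(m, p)
  m2 <- load_policy(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$vocab$tokens, m$vocab$tokens)
  expect_equal(sequence_nll(m2, "CCO"), sequence_nll(m, "CCO"))
  saveRDS(list(format = "other"), p)
  expect_error(load_policy(p), "checkpoint")
})

test_that("the fixture prior emits mostly valid SMILES", {
  prior <- fixture_prior()
  set.seed(52)
  s <- sample_batch(prior, 200L, 96L)
  expect_gte(mean(is_valid_smiles(s$smiles)), 0.95)
})
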