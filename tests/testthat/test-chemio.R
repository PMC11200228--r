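# Chemistry substrate: canonicalization, randomization, scaffolds,
# fingerprints, similarity, corpus I/O.

test_that("canonicalize maps equivalent writings to one form and flags bad input", {
  out <- canonicalize(c("c1ccccc1", "C1=CC=CC=C1"))
  expect_false(anyNA(out))
  expect_identical(out[1], out[2])

  # unparseable inputs yield NA, never an error
  expect_true(is.na(canonicalize("C(")))
  expect_true(is.na(canonicalize("c1ccccc")))
  expect_true(is.na(canonicalize("C(C)(C)(C)(C)C")))  # pentavalent carbon
  expect_true(is.na(canonicalize("C(()C")))            # empty branch
  expect_false(is_valid_smiles("CC)"))
  expect_true(is_valid_smiles("CCO"))

  # idempotence on a mixed bag of valid molecules
  mols <- c("CCO", "Cc1ccccc1", "O=C(NC)c1ccc(F)cc1", "C1CC2CCC1CC2",
            ref_molecules())
  can1 <- canonicalize(mols)
  expect_identical(canonicalize(can1), can1)
})

test_that("canonicalization of ethanol matches the pinned toolkit form", {
  # fixture pinned from the toolkit before the main build
  expect_identical(canonicalize("OCC"), "CCO")
})

test_that("randomize_smiles preserves molecular identity and is seeded", {
  fixtures <- c("CCO", "Cc1ccccc1", "Fc1ccc2c(c1)onc2C1CCNCC1",
                "O=C(N)C1CCN(CC1)c1ccncc1")
  for (s in fixtures) {
    can <- canonicalize(s)
    set.seed(42)
    for (i in 1:100) {
      expect_identical(canonicalize(randomize_smiles(s)), can)
    }
  }

  set.seed(7)
  a <- replicate(20, randomize_smiles("O=C(N)C1CCN(CC1)c1ccncc1"))
  set.seed(7)
  b <- replicate(20, randomize_smiles("O=C(N)C1CCN(CC1)c1ccncc1"))
  expect_identical(a, b)
  expect_gt(length(unique(a)), 1)  # shuffling actually varies the writing

  expect_error(randomize_smiles("C("), "invalid")
})

test_that("ethanol randomizations stay within the DFS-enumerable writings", {
  # brute force: ethanol's graph admits exactly these four DFS writings
  valid_forms <- c("CCO", "OCC", "C(C)O", "C(O)C")
  set.seed(11)
  got <- unique(replicate(60, randomize_smiles("CCO")))
  expect_true(all(got %in% valid_forms))
  expect_gt(length(got), 1)
})

test_that("benzene randomizations all canonicalize back to benzene", {
  can <- canonicalize("c1ccccc1")
  set.seed(3)
  for (i in 1:25) {
    expect_identical(canonicalize(randomize_smiles("c1ccccc1")), can)
  }
})

test_that("Bemis-Murcko scaffolds strip side chains and keep frameworks", {
  benzene <- canonicalize("c1ccccc1")
  expect_identical(scaffold("c1ccccc1"), benzene)   # its own scaffold
  expect_identical(scaffold("Cc1ccccc1"), benzene)  # toluene -> benzene
  expect_identical(scaffold("CCc1ccccc1CC"), benzene)

  # acyclic molecules use their own canonical SMILES as the key
  expect_identical(scaffold("CCO"), canonicalize("CCO"))
  expect_identical(scaffold("OCC"), canonicalize("CCO"))

  # scaffolding is idempotent
  sc <- scaffold(ref_molecules()[["risperidone"]])
  expect_identical(scaffold(sc), sc)
  # different decorations of one framework share a key
  expect_identical(scaffold("COc1ccc(C2CCNCC2)cc1"),
                   scaffold("Clc1ccc(C2CCNCC2)cc1"))
  expect_error(scaffold("C("), "invalid")
})

test_that("tanimoto has the set-overlap semantics", {
  fp <- function(bits) structure(bits, nbits = 4L, class = "morgan_fp")
  # a = 1100, b = 1010 -> 1 shared of 3 set positions
  expect_equal(tanimoto(fp(c(0L, 1L)), fp(c(0L, 2L))), 1 / 3)
  expect_equal(tanimoto(fp(c(0L, 1L)), fp(c(0L, 1L))), 1)
  expect_equal(tanimoto(fp(c(0L, 1L)), fp(c(2L, 3L))), 0)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(
    tanimoto(morgan_fp("CCO", nbits = 1024L), morgan_fp("CCO", nbits = 2048L)),
    "mismatch")
})

test_that("morgan fingerprints are deterministic, bounded and identity-preserving", {
  mols <- c("CCO", "Cc1ccccc1", "O=C(N)C1CCN(CC1)c1ccncc1")
  for (s in mols) {
    f1 <- morgan_fp(s)
    f2 <- morgan_fp(canonicalize(s))
    expect_identical(unclass(f1), unclass(f2))  # same molecule, same bits
    expect_true(all(f1 >= 0L & f1 < 2048L))
    expect_equal(tanimoto(f1, f1), 1)
  }
  set.seed(5)
  # symmetry and bounds across random pairs
  fps <- lapply(mols, morgan_fp)
  for (i in seq_along(fps)) {
    for (j in seq_along(fps)) {
      tij <- tanimoto(fps[[i]], fps[[j]])
      expect_equal(tij, tanimoto(fps[[j]], fps[[i]]))
      expect_gte(tij, 0); expect_lte(tij, 1)
    }
  }
})

test_that("smi and csv corpus round trips preserve the molecules", {
  smis <- c("CCO", "Cc1ccccc1", "O=C(N)C1CCNCC1")
  p1 <- withr::local_tempfile(fileext = ".smi")
  write_smiles(smis, p1, names = c("a", "b", "c"))
  expect_identical(read_smiles(p1), smis)

  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(smiles = smis, id = 1:3), p2,
                   row.names = FALSE)
  expect_identical(read_smiles(p2), smis)
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), p3, row.names = FALSE)
  expect_error(read_smiles(p3), "smiles")
})
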