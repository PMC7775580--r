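# Molecule primitives: parsing, canonical identity, fingerprints,
# fragments, scaffolds, properties and the fixture generator.

test_that("parser accepts valid structures and rejects chemical nonsense", {
  p <- parse_smiles(c("c1ccccc1", "C1CC", "F=F", "CCO", "not smiles"))
  expect_equal(p$valid, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_false(anyNA(p$canonical[p$valid]))
  expect_true(all(is.na(p$canonical[!p$valid])))
})

test_that("canonicalization is spelling-invariant and idempotent", {
  two <- canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(two[1], two[2])
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  once <- canonical_smiles("CN1CCC(O)CC1")
  expect_identical(canonical_smiles(once), once)
  # idempotence across a generated set
  ms <- cached_fixture(100, seed = 5)
  expect_identical(canonical_smiles(valid_smiles(ms)), valid_smiles(ms))
})

test_that("tokenizer keeps multi-character tokens whole and round-trips", {
  expect_identical(tokenize("CCl"),
                   c(BEGIN_TOKEN, "C", "Cl", END_TOKEN))
  expect_length(tokenize("c1ccccc1"), 10L)  # 8 tokens + both markers
  expect_identical(tokenize("C[nH]1%12")[2:5], c("C", "[nH]", "1", "%12"))
  expect_error(tokenize("C%1C"), "dangling")
  expect_error(tokenize("C[nH"), "unterminated")
  for (s in valid_smiles(cached_fixture(100, seed = 5))) {
    expect_identical(detokenize(tokenize(s)), s)
  }
})

test_that("morgan fingerprints are deterministic and spelling-invariant", {
  fps <- morgan_fp(c("c1ccccc1", "C1=CC=CC=C1", "C1CCCCC1"))
  expect_identical(fps[[1]], fps[[2]])          # same molecule, two spellings
  expect_false(identical(fps[[1]], fps[[3]]))   # benzene vs cyclohexane
  expect_true(all(lengths(fps) >= 1))
  expect_equal(tanimoto(fps[[1]], fps[[1]]), 1.0)
})

test_that("tanimoto matches brute-force set arithmetic on toy vectors", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(c(1L, 2L), c(5L, 9L)), 0)
  expect_error(tanimoto(rep(TRUE, 8), rep(TRUE, 16)), "mismatch")
  set.seed(42)
  for (i in 1:25) {
    a <- stats::runif(64) < 0.3
    b <- stats::runif(64) < 0.3
    brute <- if (sum(a | b) == 0) 0 else sum(a & b) / sum(a | b)
    expect_equal(tanimoto(a, b), brute)
    expect_equal(tanimoto(b, a), tanimoto(a, b))
    expect_gte(tanimoto(a, b), 0)
    expect_lte(tanimoto(a, b), 1)
  }
})

test_that("BRICS fragments form a per-molecule multiset", {
  fr <- brics_fragments(c("C", "c1ccccc1C(=O)NC1CCCCC1",
                          "c1ccccc1C(=O)NC1CCCCC1"))
  expect_identical(fr[[1]], "C")              # uncuttable: itself
  expect_gte(length(fr[[2]]), 2L)             # amide-linked two-ring cuts
  expect_identical(fr[[2]], fr[[3]])          # identical molecules
  # spelling invariance
  fr2 <- brics_fragments(c("C1CCCCC1NC(=O)c1ccccc1"))
  expect_identical(sort(fr[[2]]), sort(fr2[[1]]))
})

test_that("Bemis-Murcko scaffolds strip side chains, keep ring systems", {
  sc <- bm_scaffold(c("c1ccccc1", "CCO", "Cc1ccccc1", "CC(=O)O"))
  expect_identical(sc[1], canonical_smiles("c1ccccc1"))
  expect_identical(sc[2], "")                  # acyclic -> empty key
  expect_identical(sc[3], sc[1])               # toluene -> benzene
  expect_identical(sc[4], "")
  # invariant under re-spelling
  expect_identical(bm_scaffold("c1ccc(cc1)C"), sc[1])
})

test_that("property vectors have the documented ranges and units", {
  ms <- cached_fixture(100, seed = 5)
  pr <- mol_properties(ms)
  expect_true(all(pr$mw > 0))
  expect_true(all(pr$sa >= 1 & pr$sa <= 10))
  expect_true(all(pr$qed >= 0 & pr$qed <= 1))
  expect_equal(mol_properties("C")$mw, 16.04, tolerance = 1e-3)
})

test_that("fixture generator is deterministic, valid and scaffold-bounded", {
  a <- make_fixture_set(60, seed = 9, scaffold_pool = 12)
  b <- make_fixture_set(60, seed = 9, scaffold_pool = 12)
  expect_identical(a$source_smiles, b$source_smiles)
  expect_equal(valid_fraction(a), 1.0)
  expect_lte(length(unique(bm_scaffold(a))), 12L)
  c2 <- make_fixture_set(60, seed = 10, scaffold_pool = 12)
  expect_false(identical(a$source_smiles, c2$source_smiles))
  expect_error(make_fixture_set(0), ">= 1")
})

test_that("SMILES files and split tables round-trip", {
  ms <- cached_fixture(30, seed = 5)
  f <- withr::local_tempfile(fileext = ".smi")
  write_smiles_file(ms, f)
  back <- read_smiles_file(f)
  expect_identical(back$canonical, ms$canonical)

  tab <- withr::local_tempfile(fileext = ".csv")
  splits <- list(train = ms_head(ms, 10), test = ms_head(ms, 5),
                 test_scaffolds = ms_head(ms, 3))
  write_split_table(splits, tab)
  back2 <- read_split_table(tab)
  expect_named(back2, c("train", "test", "test_scaffolds"))
  expect_equal(length(back2$train), 10L)
  expect_identical(back2$test$canonical, splits$test$canonical)
})
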