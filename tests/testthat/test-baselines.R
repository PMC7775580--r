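# Baseline generators: n-gram, HMM (Baum-Welch), combinatorial.

test_that("ngram on a one-string corpus memorizes the string", {
  corpus <- molecule_set("CC")
  m <- ngram_fit(corpus, n = 3)   # context 2: begin-padded, deterministic
  out <- ngram_sample_many(m, 20, seed = 1)
  expect_true(all(out == "CC"))
})

test_that("ngram samples are deterministic and stay in the vocabulary", {
  corpus <- cached_fixture(100, seed = 41)
  m <- ngram_fit(corpus, n = 4)
  s1 <- ngram_sample_many(m, 50, seed = 7)
  s2 <- ngram_sample_many(m, 50, seed = 7)
  expect_identical(s1, s2)
  s3 <- ngram_sample_many(m, 50, seed = 8)
  expect_false(identical(s1, s3))
  toks <- unique(unlist(lapply(s1[nzchar(s1)], function(s) {
    t <- tokenize(s); t[-c(1, length(t))]
  })))
  expect_true(all(toks %in% m$vocabulary))
})

test_that("unigram model reproduces corpus token frequencies", {
  corpus <- cached_fixture(60, seed = 41)
  m <- ngram_fit(corpus, n = 1)
  draws <- ngram_sample_many(m, 2000, seed = 3, max_len = 500)
  # each emitted token (plus one end token per finished string) is an
  # iid draw from the unigram distribution
  toks <- unlist(lapply(draws, function(s) {
    t <- tokenize(s)
    c(t[-c(1, length(t))], END_TOKEN)
  }))
  p <- get("k", envir = m$counts)
  p <- p / sum(p)
  n <- length(toks)
  for (tok in names(p)) {
    phat <- mean(toks == tok)
    se <- sqrt(p[[tok]] * (1 - p[[tok]]) / n)
    expect_lt(abs(phat - p[[tok]]), 3 * se + 1e-12)
  }
})

test_that("Baum-Welch increases likelihood; rows stay stochastic", {
  corpus <- cached_fixture(50, seed = 42)
  m <- hmm_fit(corpus, K = 4, max_iter = 15, tol = 0, seed = 2)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_equal(sum(m$start), 1, tolerance = 1e-9)
  expect_equal(rowSums(m$trans), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(m$emit)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(m$start >= 0) && all(m$trans >= 0) && all(m$emit >= 0))
})

test_that("K=1 HMM collapses to the unigram closed form", {
  corpus <- cached_fixture(40, seed = 43)
  m <- hmm_fit(corpus, K = 1, max_iter = 5, tol = 0, seed = 1)
  seqs <- lapply(valid_smiles(corpus), function(s) {
    t <- tokenize(s)
    c(t[-c(1, length(t))], END_TOKEN)
  })
  toks <- unlist(seqs)
  freq <- table(toks)[m$vocabulary] / length(toks)
  expect_equal(unname(m$emit[1, ]), as.numeric(freq), tolerance = 1e-9)
  expect_equal(as.numeric(m$trans), 1)
  # forward likelihood equals the unigram product
  for (s in valid_smiles(corpus)[1:5]) {
    t <- tokenize(s)
    x <- c(t[-c(1, length(t))], END_TOKEN)
    expect_equal(hmm_loglik(m, s),
                 sum(log(as.numeric(freq[x]))), tolerance = 1e-9)
  }
})

test_that("hmm sampling is seeded and vocabulary-bounded", {
  corpus <- cached_fixture(50, seed = 42)
  m <- hmm_fit(corpus, K = 4, max_iter = 10, seed = 2)
  s1 <- hmm_sample_many(m, 30, seed = 5)
  expect_identical(s1, hmm_sample_many(m, 30, seed = 5))
  toks <- unlist(lapply(s1[nzchar(s1)], function(s) {
    t <- tokenize(s); t[-c(1, length(t))]
  }))
  expect_true(all(toks %in% m$vocabulary))
})

test_that("fragment library frequencies conserve counts and add up", {
  corpus <- cached_fixture(80, seed = 44)
  lib <- combinatorial_fit(corpus)
  per_mol <- brics_fragments(corpus, keep_labels = TRUE)
  expect_equal(sum(lib$fragments), length(unlist(per_mol)))
  expect_equal(sum(lib$joint_count_dist), 1)
  # doubling the corpus doubles every frequency
  lib2 <- combinatorial_fit(
    molecule_set(rep(valid_smiles(corpus), 2)))
  expect_equal(lib2$fragments[names(lib$fragments)], 2L * lib$fragments)
})

test_that("a library of uncuttable molecules returns them unchanged", {
  lib <- combinatorial_fit(molecule_set("c1ccccc1"))
  expect_identical(names(lib$fragments), "c1ccccc1")
  expect_identical(names(lib$joint_count_dist), "1")
  out <- combinatorial_sample_many(lib, 5, seed = 1)
  expect_true(all(out$canonical == "c1ccccc1"))
})

test_that("combinatorial samples are valid, seeded, and library-supported", {
  corpus <- cached_fixture(120, seed = 44)
  lib <- combinatorial_fit(corpus)
  g1 <- combinatorial_sample_many(lib, 60, seed = 9)
  expect_equal(valid_fraction(g1), 1.0)
  g2 <- combinatorial_sample_many(lib, 60, seed = 9)
  expect_identical(g1$canonical, g2$canonical)
  # sampled molecules decompose into library fragments, up to
  # attachment-point relabeling and hydrogen capping of leftovers; a
  # re-cut across a newly formed bond can occasionally merge two library
  # pieces, so coverage is asserted at 95% of fragment occurrences
  allowed <- unique(canonical_smiles(
    unlist(lapply(names(lib$fragments), cap_variants))))
  allowed <- gsub("\\[0\\*\\]", "*", allowed)
  occ <- unlist(brics_fragments(ms_head(g1, 25)))
  expect_gte(mean(occ %in% allowed), 0.95)
})
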