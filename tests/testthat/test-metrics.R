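# Evaluation metrics: counting metrics, similarity metrics, Fréchet
# distance, Wasserstein-1, and the identity battery on self-comparison.

test_that("validity, uniqueness and novelty count canonical identities", {
  G <- molecule_set(c("c1ccccc1", "C1=CC=CC=C1", "CCO", "C1CC"))
  expect_equal(valid_fraction(G), 0.75)
  expect_equal(unique_at_k(G, 3), 2 / 3)     # two spellings of benzene
  expect_equal(unique_at_k(G, 2), 1 / 2)
  dup <- molecule_set(rep("CCO", 10))
  expect_equal(unique_at_k(dup, 10), 0.1)

  train <- molecule_set(c("c1ccccc1", "CCN"))
  expect_equal(novelty(G, train), 1 / 3)     # benzene (twice of 3) known
  expect_equal(novelty(train, train), 0.0)
  expect_equal(novelty(molecule_set("CCCCC"), train), 1.0)
  expect_error(valid_fraction(molecule_set(character(0))), "empty")
  expect_error(unique_at_k(molecule_set("C1CC"), 10), "no valid")
})

test_that("substructure counts are additive and cosine similarity exact", {
  one <- molecule_set("c1ccccc1C(=O)NC1CCCCC1")
  two <- molecule_set(rep("c1ccccc1C(=O)NC1CCCCC1", 2))
  c1 <- substructure_counts(one, "fragment")
  c2 <- substructure_counts(two, "fragment")
  expect_identical(names(c1), names(c2))
  expect_equal(as.integer(c2), 2L * as.integer(c1))
  expect_equal(cosine_count_similarity(c1, c2), 1.0)  # scale-invariant

  sc <- substructure_counts(molecule_set(c("c1ccccc1", "Cc1ccccc1", "CCO")),
                            "scaffold")
  expect_equal(sc[[canonical_smiles("c1ccccc1")]], 2L)
  expect_equal(unname(sc[which(names(sc) == "")]), 1L)
  # the empty-scaffold class participates in the cosine like any other
  acyc <- molecule_set(c("CCO", "CCN"))
  expect_equal(cosine_count_similarity(
    substructure_counts(acyc, "scaffold"),
    substructure_counts(molecule_set("CCCC"), "scaffold")), 1.0)

  # hand-evaluated toy cosine
  cg <- structure(c(a = 1L, b = 1L), kind = "fragment",
                  class = "substructure_counts")
  cr <- structure(c(a = 1L), kind = "fragment",
                  class = "substructure_counts")
  expect_equal(cosine_count_similarity(cg, cr), 1 / sqrt(2))
  cd <- structure(c(z = 3L), kind = "fragment",
                  class = "substructure_counts")
  expect_equal(cosine_count_similarity(cg, cd), 0)
  bad <- structure(c(a = 1L), kind = "scaffold",
                   class = "substructure_counts")
  expect_error(cosine_count_similarity(cg, bad), "kind")
})

test_that("snn and internal diversity match brute-force oracles", {
  G <- ms_head(cached_unique_fixture(40, seed = 31), 6)
  R <- ms_subset(cached_unique_fixture(40, seed = 31), 7:15)
  fg <- morgan_fp(G)
  fr <- morgan_fp(R)
  brute_snn <- mean(vapply(fg, function(g) {
    max(vapply(fr, function(r) tanimoto(g, r), numeric(1)))
  }, numeric(1)))
  expect_equal(snn(G, R), brute_snn, tolerance = 1e-12)
  expect_equal(snn(G, G), 1.0)

  for (p in 1:2) {
    brute_id <- 1 - (mean(outer(seq_along(fg), seq_along(fg),
      Vectorize(function(i, j) tanimoto(fg[[i]], fg[[j]])^p))))^(1 / p)
    expect_equal(internal_diversity(G, p), brute_id, tolerance = 1e-12)
  }
  single <- molecule_set("CCO")
  expect_equal(internal_diversity(single, 1L), 0.0)
  expect_equal(internal_diversity(molecule_set(rep("CCO", 5)), 2L), 0.0)
})

test_that("embedding stats use sample covariance and ignore order", {
  st <- embedding_stats(matrix(c(0, 2), 2, 1))
  expect_equal(st$mu, 1)
  expect_equal(as.numeric(st$sigma), 2)   # n-1 denominator
  X <- matrix(stats::rnorm(50), 10, 5)
  st1 <- embedding_stats(X)
  st2 <- embedding_stats(X[sample(10), ])
  expect_equal(st1$mu, st2$mu)
  expect_equal(st1$sigma, st2$sigma)
  expect_equal(embedding_stats(matrix(1, 5, 3))$sigma, matrix(0, 3, 3))
  expect_error(embedding_stats(matrix(1, 1, 3)), "at least 2")
})

test_that("frechet distance matches the diagonal closed form", {
  mk <- function(mu, sig) {
    structure(list(mu = mu, sigma = sig), class = "embedding_stats")
  }
  a <- mk(c(0, 0), diag(c(1, 2)))
  expect_equal(frechet_distance(a, a), 0.0)
  b <- mk(1, matrix(4)); c1 <- mk(0, matrix(4))
  expect_equal(frechet_distance(b, c1), 1.0)  # equal variance, |dmu|^2
  set.seed(7)
  for (i in 1:10) {
    mu1 <- stats::rnorm(4); mu2 <- stats::rnorm(4)
    s1 <- stats::runif(4, 0.1, 3); s2 <- stats::runif(4, 0.1, 3)
    closed <- sum((mu1 - mu2)^2) + sum((sqrt(s1) - sqrt(s2))^2)
    expect_equal(frechet_distance(mk(mu1, diag(s1)), mk(mu2, diag(s2))),
                 closed, tolerance = 1e-9)
  }
  # symmetric on full covariances
  S1 <- crossprod(matrix(stats::rnorm(16), 4))
  S2 <- crossprod(matrix(stats::rnorm(16), 4))
  f12 <- frechet_distance(mk(numeric(4), S1), mk(numeric(4), S2))
  f21 <- frechet_distance(mk(numeric(4), S2), mk(numeric(4), S1))
  expect_equal(f12, f21, tolerance = 1e-9)
  expect_gte(f12, 0)
  expect_error(frechet_distance(b, a), "dimensions")
})

test_that("wasserstein1 solves tiny transport problems exactly", {
  expect_equal(wasserstein1(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(wasserstein1(0, 1), 1.0)
  expect_equal(wasserstein1(c(0, 1), c(1, 2)), 1.0)
  expect_equal(wasserstein1(c(0, 1), c(0, 1, 1)), 1 / 6)
  set.seed(11)
  for (i in 1:10) {
    x <- stats::rnorm(40); y <- stats::rnorm(40, 0.5)
    # equal-size samples: W1 is the mean absolute quantile difference
    expect_equal(wasserstein1(x, y), mean(abs(sort(x) - sort(y))),
                 tolerance = 1e-9)
    expect_equal(wasserstein1(x, y), wasserstein1(y, x))
  }
})

test_that("every metric is invariant under SMILES re-spelling", {
  s1 <- c("c1ccccc1C", "OCC", "C1=CC=CC=C1", "CC(=O)NC1CCCCC1")
  s2 <- c("Cc1ccccc1", "CCO", "c1ccccc1", "O=C(C)NC1CCCCC1")
  G1 <- molecule_set(s1); G2 <- molecule_set(s2)
  R <- cached_unique_fixture(40, seed = 31)
  expect_identical(G1$canonical, G2$canonical)
  expect_equal(snn(G1, R), snn(G2, R))
  expect_equal(
    cosine_count_similarity(substructure_counts(G1, "fragment"),
                            substructure_counts(R, "fragment")),
    cosine_count_similarity(substructure_counts(G2, "fragment"),
                            substructure_counts(R, "fragment")))
  expect_equal(mol_properties(G1), mol_properties(G2))
})

test_that("duplicating every molecule leaves shape metrics unchanged", {
  G <- ms_head(cached_unique_fixture(40, seed = 31), 8)
  G2 <- molecule_set(rep(valid_smiles(G), each = 2))
  R <- ms_subset(cached_unique_fixture(40, seed = 31), 9:20)
  expect_equal(snn(G2, R), snn(G, R))
  expect_equal(internal_diversity(G2, 1L), internal_diversity(G, 1L))
  expect_equal(internal_diversity(G2, 2L), internal_diversity(G, 2L))
  for (kind in c("fragment", "scaffold")) {
    expect_equal(
      cosine_count_similarity(substructure_counts(G2, kind),
                              substructure_counts(R, kind)),
      cosine_count_similarity(substructure_counts(G, kind),
                              substructure_counts(R, kind)))
  }
})

test_that("evaluate computes the full battery with self-identities", {
  ms <- cached_fixture(120, seed = 33)
  rep <- evaluate(ms, train = ms, test = ms, cfg = cached_cfg())
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$valid, 1.0)
  expect_equal(rep$novelty, 0.0)
  expect_equal(rep$filters, 1.0)
  expect_equal(rep$frag_test, 1.0, tolerance = 1e-12)
  expect_equal(rep$scaff_test, 1.0, tolerance = 1e-12)
  expect_equal(rep$snn_test, 1.0)
  expect_equal(rep$fcd_test, 0.0, tolerance = 1e-9)
  expect_true(all(rep$property_w1 == 0))
  flat <- flatten_report(rep)
  expect_false("Scaf/TestSF" %in% names(flat))  # no scaffold split given
  # bounds on every unit-interval metric
  unit <- flat[setdiff(names(flat), c("FCD/Test", "W1/MW", "W1/LogP",
                                      "W1/SA", "W1/QED"))]
  expect_true(all(unit >= 0 & unit <= 1))
})

test_that("evaluate reports testsf columns against a scaffold split", {
  ds <- build_dataset(cached_fixture(400, seed = 22), cached_cfg(),
                      quiet = TRUE)
  sp <- scaffold_split(ds, scaffold_frac = 0.15, test_frac = 0.1, seed = 4)
  rep <- evaluate(sp$train, train = sp$train, test = sp$test,
                  test_scaffolds = sp$scaffold_test, cfg = cached_cfg())
  expect_equal(rep$scaff_testsf, 0.0)   # held-out scaffolds by design
  expect_true(rep$scaff_test > 0)
  expect_true(is.finite(rep$fcd_testsf))
})
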