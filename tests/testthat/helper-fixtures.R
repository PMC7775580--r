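# Shared fixtures, memoized so each synthetic set and filter config is
# built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(n, seed, pool = 30L) {
  key <- sprintf("f_%d_%d_%d", n, seed, pool)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture_set(n, seed = seed,
                                              scaffold_pool = pool)
  }
  .fixture_cache[[key]]
}

cached_cfg <- function() {
  if (is.null(.fixture_cache$cfg)) .fixture_cache$cfg <- filter_config()
  .fixture_cache$cfg
}

# a small set of duplicate-free molecules (distinct canonical SMILES)
cached_unique_fixture <- function(n, seed, pool = 30L) {
  key <- sprintf("u_%d_%d_%d", n, seed, pool)
  if (is.null(.fixture_cache[[key]])) {
    ms <- cached_fixture(4L * n, seed, pool)
    smi <- unique(ms$canonical)
    stopifnot(length(smi) >= n)
    .fixture_cache[[key]] <- molecule_set(smi[seq_len(n)],
                                          provenance = "unique-fixture")
  }
  .fixture_cache[[key]]
}

ms_head <- function(ms, n) ms_subset(ms, seq_len(n))

# all hydrogen-capped variants of a labeled BRICS fragment key: every
# subset of its attachment points replaced by H (what the combinatorial
# sampler does to leftover attachment points)
cap_variants <- function(key) {
  m <- gregexpr("\\[[0-9]+\\*\\]", key)[[1]]
  if (m[1] == -1) return(key)
  k <- length(m)
  out <- character(0)
  for (mask in 0:(2^k - 1)) {
    s <- key
    for (i in rev(seq_len(k))) {
      rep <- if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) > 0) "[H]" else "[0*]"
      s <- paste0(substr(s, 1, m[i] - 1), rep,
                  substr(s, m[i] + attr(m, "match.length")[i], nchar(s)))
    }
    out <- c(out, s)
  }
  out
}
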