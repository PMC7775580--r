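# N-gram SMILES language model: token n-gram frequency counts with
# stupid backoff to shorter contexts, sampled token-by-token.

.ctx_sep <- "\x1f"
# "k" prefix keeps the empty (unigram) context a legal environment name
.ctx_key <- function(ctx) paste(c("k", ctx), collapse = .ctx_sep)

#' Fit an n-gram model on a SMILES corpus
#'
#' Accumulates token n-gram counts (orders 1..n) over the tokenized
#' canonical SMILES of the corpus, with begin padding and an explicit
#' end-of-string token. Sampling backs off to the longest observed
#' context.
#'
#' @param corpus a `molecule_set` (valid molecules are used).
#' @param n maximum n-gram order (context length n-1).
#' @return an `ngram_model`.
#' @export
ngram_fit <- function(corpus, n = 5L) {
  stopifnot(inherits(corpus, "molecule_set"), n >= 1L)
  smi <- valid_smiles(corpus)
  if (length(smi) == 0L) stop("ngram_fit: empty corpus")
  n <- as.integer(n)
  counts <- new.env(parent = emptyenv())
  vocab <- character(0)
  for (s in smi) {
    toks <- tokenize(s)
    core <- c(toks[-c(1L, length(toks))], END_TOKEN)
    vocab <- union(vocab, core)
    padded <- c(rep(BEGIN_TOKEN, n - 1L), core)
    for (i in seq_along(core)) {
      pos <- i + n - 1L          # position of the target in `padded`
      tgt <- padded[pos]
      for (L in 0:(n - 1L)) {
        key <- .ctx_key(if (L == 0L) character(0)
                        else padded[(pos - L):(pos - 1L)])
        v <- if (exists(key, envir = counts, inherits = FALSE)) {
          get(key, envir = counts)
        } else {
          numeric(0)
        }
        v[tgt] <- (if (is.na(v[tgt])) 0 else v[tgt]) + 1
        assign(key, v, envir = counts)
      }
    }
  }
  structure(list(n = n, counts = counts, vocabulary = vocab),
            class = "ngram_model")
}

# distribution for the next token under stupid backoff
.ngram_next <- function(model, ctx) {
  for (L in seq(length(ctx), 0L)) {
    key <- .ctx_key(if (L == 0L) character(0)
                    else ctx[(length(ctx) - L + 1L):length(ctx)])
    if (exists(key, envir = model$counts, inherits = FALSE)) {
      v <- get(key, envir = model$counts)
      if (sum(v) > 0) return(v / sum(v))
    }
  }
  stop("ngram model has no unigram counts")  # cannot happen after fit
}

#' Sample SMILES strings from an n-gram model
#'
#' Sequential token sampling until the end token or `max_len` tokens.
#' The output strings carry no validity guarantee: syntactically or
#' chemically broken strings are the expected failure mode, measured by
#' [valid_fraction()].
#'
#' @param model an `ngram_model`.
#' @param max_len maximum number of tokens per string.
#' @param seed integer RNG seed.
#' @param n_samples number of strings (`ngram_sample()` returns one).
#' @return character vector of sampled strings.
#' @export
ngram_sample_many <- function(model, n_samples, seed = 1L, max_len = 100L) {
  stopifnot(inherits(model, "ngram_model"))
  with_seed(seed, {
    vapply(seq_len(n_samples), function(i) .ngram_draw(model, max_len),
           character(1))
  })
}

#' @rdname ngram_sample_many
#' @export
ngram_sample <- function(model, max_len = 100L, seed = 1L) {
  ngram_sample_many(model, 1L, seed = seed, max_len = max_len)
}

.ngram_draw <- function(model, max_len) {
  ctx <- rep(BEGIN_TOKEN, model$n - 1L)
  out <- character(0)
  for (i in seq_len(max_len)) {
    p <- .ngram_next(model, ctx)
    tok <- sample(names(p), 1L, prob = p)
    if (tok == END_TOKEN) break
    out <- c(out, tok)
    keep <- model$n - 1L
    ctx <- if (keep == 0L) character(0) else utils::tail(c(ctx, tok), keep)
  }
  paste(out, collapse = "")
}
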