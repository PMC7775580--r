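# Hidden Markov model over SMILES token sequences, trained with
# Baum-Welch (scaled forward-backward EM) and sampled ancestrally.

#' Fit an HMM on a SMILES corpus with Baum-Welch
#'
#' Discrete-emission HMM over the token vocabulary (including an
#' explicit end-of-string token). Expectation-maximization with scaled
#' forward-backward; iteration stops when the total log-likelihood
#' improves by less than `tol` or after `max_iter` iterations. The
#' per-iteration log-likelihood trace is returned and is non-decreasing
#' (standard EM guarantee).
#'
#' @param corpus a `molecule_set` (valid molecules are used).
#' @param K number of hidden states.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the total log-likelihood.
#' @param seed integer seed for the random initialization.
#' @return an `hmm_model`: start/transition/emission probabilities,
#'   vocabulary and `loglik_trace`.
#' @export
hmm_fit <- function(corpus, K = 16L, max_iter = 50L, tol = 1e-3, seed = 1L) {
  stopifnot(inherits(corpus, "molecule_set"))
  if (K < 1L) stop("hmm_fit: K must be >= 1")
  smi <- valid_smiles(corpus)
  if (length(smi) == 0L) stop("hmm_fit: empty corpus")
  K <- as.integer(K)

  seqs_tok <- lapply(smi, function(s) {
    toks <- tokenize(s)
    c(toks[-c(1L, length(toks))], END_TOKEN)
  })
  vocab <- sort(unique(unlist(seqs_tok)))
  V <- length(vocab)
  seqs <- lapply(seqs_tok, function(t) match(t, vocab))
  # weight duplicate token sequences instead of re-running them
  key <- vapply(seqs, paste, character(1), collapse = ",")
  tab <- table(key)
  useq <- seqs[!duplicated(key)]
  w <- as.numeric(tab[key[!duplicated(key)]])

  init_rows <- function(nr, nc) {
    m <- matrix(stats::runif(nr * nc, 0.5, 1.5), nr, nc)
    m / rowSums(m)
  }
  params <- with_seed(seed, list(
    start = as.vector(init_rows(1L, K)),
    trans = init_rows(K, K),
    emit = init_rows(K, V)
  ))
  start <- params$start; trans <- params$trans; emit <- params$emit

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    start_acc <- numeric(K)
    trans_acc <- matrix(0, K, K)
    emit_acc <- matrix(0, K, V)
    for (si in seq_along(useq)) {
      x <- useq[[si]]
      Tn <- length(x)
      B <- emit[, x, drop = FALSE]              # K x T
      alpha <- matrix(0, K, Tn)
      cvec <- numeric(Tn)
      a <- start * B[, 1L]
      cvec[1L] <- sum(a)
      alpha[, 1L] <- a / cvec[1L]
      if (Tn > 1L) for (t in 2:Tn) {
        a <- as.vector(crossprod(trans, alpha[, t - 1L])) * B[, t]
        cvec[t] <- sum(a)
        alpha[, t] <- a / cvec[t]
      }
      beta <- matrix(0, K, Tn)
      beta[, Tn] <- 1
      if (Tn > 1L) for (t in (Tn - 1L):1L) {
        beta[, t] <- as.vector(trans %*% (B[, t + 1L] * beta[, t + 1L])) /
          cvec[t + 1L]
      }
      g <- alpha * beta                          # already normalized per t
      ll <- ll + w[si] * sum(log(cvec))
      start_acc <- start_acc + w[si] * g[, 1L]
      for (t in seq_len(Tn)) {
        emit_acc[, x[t]] <- emit_acc[, x[t]] + w[si] * g[, t]
      }
      if (Tn > 1L) for (t in 1:(Tn - 1L)) {
        xi <- trans * outer(alpha[, t], B[, t + 1L] * beta[, t + 1L]) /
          cvec[t + 1L]
        trans_acc <- trans_acc + w[si] * xi
      }
    }
    trace <- c(trace, ll)
    norm_rows <- function(m) {
      rs <- rowSums(m)
      bad <- rs <= 0
      m[bad, ] <- 1
      rs[bad] <- ncol(m)
      m / rs
    }
    start <- start_acc / sum(start_acc)
    trans <- norm_rows(trans_acc)
    emit <- norm_rows(emit_acc)
    if (iter > 1L && (trace[iter] - trace[iter - 1L]) < tol) break
  }

  structure(list(K = K, start = start, trans = trans,
                 emit = `colnames<-`(emit, vocab), vocabulary = vocab,
                 loglik_trace = trace),
            class = "hmm_model")
}

#' Log-likelihood of SMILES strings under a fitted HMM
#'
#' Forward-algorithm likelihood (token sequence terminated with the
#' end-of-string token). Strings with tokens outside the model
#' vocabulary score `-Inf`.
#'
#' @param model an `hmm_model`.
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of log-likelihoods.
#' @export
hmm_loglik <- function(model, smiles) {
  vapply(smiles, function(s) {
    toks <- tokenize(s)
    x <- match(c(toks[-c(1L, length(toks))], END_TOKEN), model$vocabulary)
    if (anyNA(x)) return(-Inf)
    a <- model$start * model$emit[, x[1L]]
    ll <- 0
    for (t in seq_along(x)) {
      if (t > 1L) {
        a <- as.vector(crossprod(model$trans, a)) * model$emit[, x[t]]
      }
      s1 <- sum(a)
      if (s1 <= 0) return(-Inf)
      ll <- ll + log(s1)
      a <- a / s1
    }
    ll
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample SMILES strings from a fitted HMM
#'
#' Ancestral sampling: draw the first state from the start distribution,
#' then alternately emit a token and transition, until the end token or
#' `max_len` tokens. No validity guarantee.
#'
#' @param model an `hmm_model`.
#' @param max_len maximum number of tokens per string.
#' @param seed integer RNG seed.
#' @param n_samples number of strings (`hmm_sample()` returns one).
#' @return character vector of sampled strings.
#' @export
hmm_sample_many <- function(model, n_samples, seed = 1L, max_len = 100L) {
  stopifnot(inherits(model, "hmm_model"))
  V <- length(model$vocabulary)
  with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      s <- sample.int(model$K, 1L, prob = model$start)
      out <- character(0)
      for (t in seq_len(max_len)) {
        tok <- model$vocabulary[sample.int(V, 1L, prob = model$emit[s, ])]
        if (tok == END_TOKEN) break
        out <- c(out, tok)
        s <- sample.int(model$K, 1L, prob = model$trans[s, ])
      }
      paste(out, collapse = "")
    }, character(1))
  })
}

#' @rdname hmm_sample_many
#' @export
hmm_sample <- function(model, max_len = 100L, seed = 1L) {
  hmm_sample_many(model, 1L, seed = seed, max_len = max_len)
}
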