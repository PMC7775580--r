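# Combinatorial generator: BRICS-decompose the training corpus into a
# fragment library, then build new molecules by drawing fragments
# according to their corpus frequencies and connecting them at random
# compatible attachment points. Assembly enforces valence, so every
# emitted molecule is chemically valid by construction.

#' Fit a BRICS fragment library on a corpus
#'
#' Decomposes every valid molecule into its BRICS fragment multiset
#' (attachment-point labels preserved, unlike the label-stripped keys
#' used by the fragment-similarity metric), accumulates fragment
#' frequencies, and records the empirical distribution of
#' fragments-per-molecule.
#'
#' @param corpus a `molecule_set`.
#' @return a `fragment_library`: `fragments` (named frequency counts),
#'   `joint_count_dist` (named probabilities over fragments-per-molecule)
#'   and `attachment_rules` (a label describing the connection policy).
#' @export
combinatorial_fit <- function(corpus) {
  stopifnot(inherits(corpus, "molecule_set"))
  if (n_valid(corpus) == 0L) stop("combinatorial_fit: empty corpus")
  per_mol <- brics_fragments(corpus, keep_labels = TRUE)
  freq <- table(unlist(per_mol, use.names = FALSE))
  cnt <- table(lengths(per_mol))
  structure(
    list(fragments = stats::setNames(as.integer(freq), names(freq)),
         joint_count_dist = stats::setNames(
           as.numeric(cnt) / sum(cnt), names(cnt)),
         attachment_rules = "single-bond join at any attachment-point pair"),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf(
    "<fragment_library> %d distinct fragments (%d occurrences), %s-%s fragments/molecule\n",
    length(x$fragments), sum(x$fragments),
    names(x$joint_count_dist)[1],
    names(x$joint_count_dist)[length(x$joint_count_dist)]))
  invisible(x)
}

#' Sample molecules from a fragment library
#'
#' For each molecule: draw a fragment count from the fragments-per-
#' molecule distribution, draw that many fragments proportional to their
#' corpus frequencies, and connect them sequentially at uniformly chosen
#' attachment-point pairs; leftover attachment points are hydrogen-
#' capped. Chemically impossible assemblies are rejected and redrawn, so
#' the returned molecules are always valid. Deterministic given `seed`.
#'
#' @param lib a `fragment_library`.
#' @param n_samples number of molecules to generate.
#' @param seed integer RNG seed.
#' @param max_attempts redraw rounds allowed before giving up on a
#'   sample (an error here signals an impoverished library).
#' @return `combinatorial_sample_many()` a `molecule_set` of `n_samples`
#'   valid molecules; `combinatorial_sample()` a single-molecule set.
#' @export
combinatorial_sample_many <- function(lib, n_samples, seed = 1L,
                                      max_attempts = 20L) {
  stopifnot(inherits(lib, "fragment_library"), n_samples >= 1L)
  frag_names <- names(lib$fragments)
  frag_w <- as.numeric(lib$fragments)
  cnt_vals <- as.integer(names(lib$joint_count_dist))
  cnt_p <- as.numeric(lib$joint_count_dist)
  with_seed(seed, {
    draw_job <- function() {
      k <- sample(cnt_vals, 1L, prob = cnt_p)
      sample(frag_names, k, replace = TRUE, prob = frag_w)
    }
    result <- rep(NA_character_, n_samples)
    pending <- seq_len(n_samples)
    for (round in seq_len(max_attempts)) {
      jobs <- replicate(length(pending), draw_job(), simplify = FALSE)
      seeds <- sample.int(.Machine$integer.max, length(pending))
      got <- backend_assemble(jobs, seeds)
      result[pending] <- got
      pending <- pending[is.na(got)]
      if (length(pending) == 0L) break
    }
    if (length(pending) > 0L) {
      stop("combinatorial sampler failed for ", length(pending),
           " molecules after ", max_attempts,
           " attempts (impoverished fragment library?)")
    }
    # the backend emits canonical SMILES and re-parses before returning,
    # so the strings are valid canonical forms already
    new_molecule_set(result, rep(TRUE, n_samples), result,
                     provenance = sprintf("combinatorial(seed=%d)", seed))
  })
}

#' @rdname combinatorial_sample_many
#' @export
combinatorial_sample <- function(lib, seed = 1L, max_attempts = 20L) {
  combinatorial_sample_many(lib, 1L, seed = seed,
                            max_attempts = max_attempts)
}
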