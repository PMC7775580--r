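# Dataset construction: structural filter rules and the three-way
# train / test / scaffold-test split.

#' Dataset-construction filter configuration
#'
#' The filter battery applied when assembling a training collection:
#' no formally charged atoms (sidesteps tautomer/pH ambiguity), elements
#' restricted to C/N/S/O/F/Cl/Br/H, no ring larger than eight atoms, and
#' no match to the medicinal-chemistry (MCF) or PAINS SMARTS patterns.
#' The packaged SMARTS lists are documented stand-ins; pass file paths or
#' character vectors to substitute any published catalog.
#'
#' @param mcf,pains SMARTS lists: a file path (one pattern per line, `#`
#'   comments allowed), a character vector of patterns, or `NULL` for the
#'   packaged stand-in lists.
#' @param allowed_elements permitted element symbols.
#' @param max_ring_size largest allowed smallest-set-of-smallest-rings
#'   ring size.
#' @param forbid_charges reject molecules with formally charged atoms.
#' @param mw_range,max_rotatable,max_xlogp optional lead-likeness
#'   pre-filters (molecular-weight window in Da, rotatable-bond cap,
#'   Crippen logP cap) of the kind used by upstream lead-like source
#'   collections; all `NULL` (off) by default.
#' @return a `filter_config` object. All SMARTS are compile-checked at
#'   construction.
#' @export
filter_config <- function(mcf = NULL, pains = NULL,
                          allowed_elements = c("C", "N", "S", "O",
                                               "F", "Cl", "Br", "H"),
                          max_ring_size = 8L, forbid_charges = TRUE,
                          mw_range = NULL, max_rotatable = NULL,
                          max_xlogp = NULL) {
  load_patterns <- function(x, default_file) {
    if (is.null(x)) {
      x <- system.file("extdata", default_file, package = "molbench",
                       mustWork = TRUE)
    }
    if (length(x) == 1L && file.exists(x)) read_smarts_file(x) else as.character(x)
  }
  if (!is.null(mw_range)) stopifnot(length(mw_range) == 2L,
                                    mw_range[1] <= mw_range[2])
  cfg <- structure(
    list(allowed_elements = allowed_elements,
         max_ring_size = as.integer(max_ring_size),
         forbid_charges = isTRUE(forbid_charges),
         mcf = load_patterns(mcf, "mcf_standin.smarts"),
         pains = load_patterns(pains, "pains_standin.smarts"),
         mw_range = mw_range, max_rotatable = max_rotatable,
         max_xlogp = max_xlogp),
    class = "filter_config"
  )
  # compile-check every SMARTS now (backend raises on a bad pattern)
  backend_filters(character(0), cfg)
  cfg
}

#' Apply the dataset filters to molecules
#'
#' @param x a `molecule_set` or character vector of SMILES.
#' @param cfg a [filter_config()].
#' @return data.frame with columns `smiles`, `pass` and a list-column
#'   `reasons` naming every violated rule (`charge`, `element`,
#'   `ring_size`, `mcf`, `pains`; `invalid` for unparsable entries).
#' @export
passes_filters <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  smi <- if (inherits(x, "molecule_set")) x$source_smiles else as.character(x)
  reasons <- backend_filters(smi, cfg)
  data.frame(smiles = smi,
             pass = lengths(reasons) == 0L,
             reasons = I(reasons),
             stringsAsFactors = FALSE)
}

#' Build a filtered, deduplicated dataset
#'
#' Keeps the ordered subset of valid molecules that pass every filter
#' rule, deduplicated by canonical SMILES (first occurrence kept). The
#' per-rule rejection counts are reported via `message()` and attached as
#' attribute `"rejection_log"`.
#'
#' @param ms a `molecule_set`.
#' @param cfg a [filter_config()].
#' @param quiet suppress the log messages.
#' @return a `molecule_set` of the retained molecules.
#' @export
build_dataset <- function(ms, cfg = filter_config(), quiet = FALSE) {
  stopifnot(inherits(ms, "molecule_set"))
  reasons <- backend_filters(ms$source_smiles, cfg)
  reasons[!ms$valid] <- list("invalid")
  pass <- ms$valid & lengths(reasons) == 0L
  dup <- pass & duplicated(ifelse(pass, ms$canonical, NA))
  keep <- pass & !dup
  log <- c(
    input = length(ms),
    table(factor(unlist(reasons),
                 levels = c("invalid", "charge", "element", "ring_size",
                            "mcf", "pains", "mw_range", "rotatable_bonds",
                            "xlogp"))),
    duplicate = sum(dup),
    kept = sum(keep)
  )
  if (!quiet) {
    message("build_dataset: ",
            paste(names(log), log, sep = ":", collapse = " "))
  }
  out <- ms_subset(ms, which(keep))
  out$provenance <- paste0(ms$provenance, "/filtered")
  attr(out, "rejection_log") <- log
  out
}

#' Scaffold-held-out three-way split
#'
#' Partitions a (deduplicated, all-valid) molecule set into train, test
#' and scaffold-test subsets. Bemis-Murcko scaffold classes are drawn
#' uniformly at random and accumulated greedily until the molecules they
#' cover reach at least `scaffold_frac` of the data; all those molecules
#' form the scaffold-test set, so no scaffold in it occurs in train or
#' test. A uniform random `test_frac` fraction of the remainder forms the
#' test set; the rest is train. Deterministic given `seed`.
#'
#' @param ms a `molecule_set`; all entries must be valid and distinct by
#'   canonical SMILES (use [build_dataset()] first).
#' @param scaffold_frac target fraction of molecules held out by
#'   scaffold.
#' @param test_frac fraction of the non-held-out molecules assigned to
#'   the random test set.
#' @param seed integer RNG seed.
#' @return a `split_result`: list with `molecule_set`s `train`, `test`,
#'   `scaffold_test`, and `held_out_scaffolds` (character vector of
#'   scaffold keys). Attribute `"flagged"` is `TRUE` when the achieved
#'   held-out fraction overshoots the target by more than half the
#'   target (one giant scaffold class).
#' @export
scaffold_split <- function(ms, scaffold_frac = 0.1, test_frac = 0.1,
                           seed = 1L) {
  stopifnot(inherits(ms, "molecule_set"),
            scaffold_frac > 0, scaffold_frac < 1,
            test_frac > 0, test_frac < 1)
  if (!all(ms$valid)) stop("scaffold_split expects an all-valid set")
  if (anyDuplicated(ms$canonical)) {
    stop("scaffold_split expects a deduplicated set")
  }
  n <- length(ms)
  scaff <- bm_scaffold(ms)
  classes <- split(seq_len(n), scaff)
  target <- ceiling(scaffold_frac * n)
  res <- with_seed(seed, {
    ord <- sample.int(length(classes))
    sizes <- cumsum(lengths(classes)[ord])
    k <- which(sizes >= target)[1]
    if (is.na(k)) k <- length(classes)
    held_classes <- ord[seq_len(k)]
    sf_idx <- sort(unlist(classes[held_classes], use.names = FALSE))
    rest <- setdiff(seq_len(n), sf_idx)
    n_test <- round(test_frac * length(rest))
    test_idx <- sort(sample(rest, n_test))
    list(sf = sf_idx, test = test_idx,
         train = setdiff(rest, test_idx),
         held = names(classes)[held_classes])
  })
  achieved <- length(res$sf) / n
  flagged <- achieved > scaffold_frac * 1.5
  if (flagged) {
    warning(sprintf(
      "scaffold_split: held-out fraction %.3f overshoots target %.3f ",
      achieved, scaffold_frac),
      "(large scaffold classes); proceeding with closest achievable")
  }
  out <- structure(
    list(train = ms_subset(ms, res$train),
         test = ms_subset(ms, res$test),
         scaffold_test = ms_subset(ms, res$sf),
         held_out_scaffolds = res$held),
    class = "split_result"
  )
  out$train$provenance <- "train"
  out$test$provenance <- "test"
  out$scaffold_test$provenance <- "test_scaffolds"
  attr(out, "flagged") <- flagged
  out
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> train %d | test %d | scaffold_test %d (%d held-out scaffolds)\n",
    length(x$train), length(x$test), length(x$scaffold_test),
    length(x$held_out_scaffolds)))
  invisible(x)
}
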