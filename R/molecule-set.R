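#' An ordered multiset of molecules with per-entry validity
#'
#' A `molecule_set` keeps every input SMILES in its original order —
#' including duplicates and unparsable strings — because generation-order
#' metrics (Unique@k) and per-draw fractions (validity, novelty) depend on
#' both. Each entry is parsed with a valence- and aromaticity-checking
#' parser; entries that fail are retained with `valid = FALSE` and a
#' missing canonical SMILES.
#'
#' @param smiles character vector of SMILES strings, one molecule per entry.
#' @param provenance short label describing where the set came from.
#' @return An object of class `molecule_set` with fields `source_smiles`,
#'   `valid` (logical), `canonical` (canonical SMILES, `NA` for invalid
#'   entries) and `provenance`.
#' @examples
#' \dontrun{
#' ms <- molecule_set(c("c1ccccc1", "C1CC", "CCO"), provenance = "demo")
#' valid_fraction(ms)  # 2/3
#' }
#' @export
molecule_set <- function(smiles, provenance = "") {
  stopifnot(is.character(smiles))
  p <- backend_parse(smiles)
  new_molecule_set(smiles, p$valid, p$canonical, provenance)
}

# trusted constructor: canonical/valid already established
new_molecule_set <- function(source_smiles, valid, canonical, provenance = "") {
  structure(
    list(source_smiles = source_smiles, valid = valid, canonical = canonical,
         provenance = provenance, cache = new.env(parent = emptyenv())),
    class = "molecule_set"
  )
}

#' @export
length.molecule_set <- function(x) length(x$source_smiles)

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set> %d entries (%d valid)%s\n",
              length(x), sum(x$valid),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Canonical SMILES of the valid entries of a set
#'
#' Order and duplicates are preserved; invalid entries are dropped.
#' @param ms a `molecule_set`.
#' @return character vector of canonical SMILES.
#' @export
valid_smiles <- function(ms) {
  stopifnot(inherits(ms, "molecule_set"))
  ms$canonical[ms$valid]
}

n_valid <- function(ms) sum(ms$valid)

# subset of entries, preserving order; feature cache is not carried over
ms_subset <- function(ms, idx) {
  new_molecule_set(ms$source_smiles[idx], ms$valid[idx], ms$canonical[idx],
                   ms$provenance)
}

# Lazily computed per-molecule features over the VALID entries, cached on
# the set. `fields` from: fp, frags, frags_labeled, scaffold, props,
# descriptors. Returns a list keyed by field, aligned with valid_smiles(ms).
ms_features <- function(ms, fields) {
  stopifnot(inherits(ms, "molecule_set"))
  missing <- fields[!vapply(fields, exists, logical(1), envir = ms$cache)]
  if (length(missing) > 0L) {
    smi <- valid_smiles(ms)
    if (length(smi) == 0L) stop("molecule_set has no valid molecules")
    got <- backend_mol_info(smi, missing)
    for (f in missing) assign(f, got[[f]], envir = ms$cache)
  }
  stats::setNames(lapply(fields, get, envir = ms$cache), fields)
}
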