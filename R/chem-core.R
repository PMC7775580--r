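# Molecule-level primitives: parsing, canonical identity, fingerprints,
# fragments, scaffolds and drug-likeness descriptors.

#' Parse SMILES with validity checking
#'
#' A string is valid iff it encodes a chemically consistent structure
#' (atom valences, aromatic-ring bond consistency). Malformed or
#' chemically impossible strings yield `valid = FALSE` rather than an
#' error.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `valid`, `canonical`
#'   (`NA` where invalid).
#' @export
parse_smiles <- function(smiles) {
  p <- backend_parse(smiles)
  data.frame(smiles = smiles, valid = p$valid, canonical = p$canonical,
             stringsAsFactors = FALSE)
}

#' Canonical SMILES
#'
#' Deterministic canonicalization: any two spellings of the same molecule
#' map to the same string, and the map is idempotent. Invalid input gives
#' `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` for invalid input).
#' @export
canonical_smiles <- function(smiles) {
  backend_parse(smiles)$canonical
}

#' Morgan (extended-connectivity) fingerprints
#'
#' Radius-2, 1024-bit circular fingerprints, the standard choice for
#' Tanimoto-based similarity in distribution-learning benchmarks.
#'
#' @param x a `molecule_set` or a character vector of valid SMILES.
#' @return a `fingerprint_set`: list of sorted 0-based on-bit index
#'   vectors with attribute `nbits = 1024`.
#' @export
morgan_fp <- function(x) {
  fps <- if (inherits(x, "molecule_set")) {
    ms_features(x, "fp")$fp
  } else {
    backend_mol_info(as.character(x), "fp")$fp
  }
  structure(fps, nbits = 1024L, class = "fingerprint_set")
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' Intersection over union of the set bits. Two all-zero vectors are
#' defined to have similarity 0 (the 0/0 case cannot arise for valid
#' molecules, whose fingerprints always have at least one bit set).
#'
#' @param a,b fingerprints: either logical/0-1 vectors of equal length, or
#'   integer vectors of set-bit indices (with equal `nbits` attributes if
#'   present).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  # logical vectors are dense bit vectors; integer vectors are set-bit
  # index sets
  to_bits <- function(x) if (is.logical(x)) which(x) else as.integer(x)
  if (is.logical(a) != is.logical(b)) {
    stop("mixed fingerprint representations")
  }
  if (is.logical(a) && length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  na <- attr(a, "nbits"); nb <- attr(b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprint length mismatch: ", na, " vs ", nb)
  }
  sa <- to_bits(a); sb <- to_bits(b)
  u <- length(union(sa, sb))
  if (u == 0L) return(0)
  length(intersect(sa, sb)) / u
}

# dense n x nbits 0/1 matrix from a list of on-bit index vectors (0-based)
fp_matrix <- function(fps, nbits = 1024L) {
  n <- length(fps)
  m <- matrix(0, n, nbits)
  for (i in seq_len(n)) m[i, fps[[i]] + 1L] <- 1
  m
}

# full pairwise Tanimoto matrix via bit-count linear algebra
tanimoto_matrix <- function(fps_a, fps_b, nbits = 1024L) {
  A <- fp_matrix(fps_a, nbits)
  B <- fp_matrix(fps_b, nbits)
  inter <- tcrossprod(A, B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  sim
}

#' BRICS fragment multiset of each molecule
#'
#' Decomposes each molecule at the 16 BRICS bond types and returns the
#' fragment multiset (an uncuttable molecule yields itself as its only
#' fragment). Attachment points are normalized to a single generic
#' wildcard before canonicalization, so the same chemical fragment cut
#' under different rules counts as one key.
#'
#' @param x a `molecule_set` or a character vector of valid SMILES.
#' @param keep_labels keep BRICS attachment-point labels (used by the
#'   combinatorial generator, which must know where fragments may join).
#' @return list of character vectors of fragment keys, one per molecule.
#' @export
brics_fragments <- function(x, keep_labels = FALSE) {
  field <- if (keep_labels) "frags_labeled" else "frags"
  if (inherits(x, "molecule_set")) {
    ms_features(x, field)[[field]]
  } else {
    backend_mol_info(as.character(x), field)[[field]]
  }
}

#' Bemis-Murcko scaffold of each molecule
#'
#' The framework of a molecule: all rings plus the linkers connecting
#' them, with side chains removed (exocyclic double-bonded atoms such as
#' ring-attached carbonyl oxygens are retained). Acyclic molecules map to
#' the distinguished empty-scaffold key `""`, which is counted as a
#' scaffold class of its own.
#'
#' @param x a `molecule_set` or a character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for
#'   acyclic molecules).
#' @export
bm_scaffold <- function(x) {
  if (inherits(x, "molecule_set")) {
    ms_features(x, "scaffold")$scaffold
  } else {
    backend_mol_info(as.character(x), "scaffold")$scaffold
  }
}

#' Physicochemical property vector
#'
#' Four properties used for distribution comparison: molecular weight
#' (Da, implicit hydrogens included), Crippen logP, synthetic
#' accessibility score (1 = easy to 10 = hard, fragment-contribution
#' heuristic) and QED drug-likeness (0-1 desirability composite).
#'
#' @param x a `molecule_set` or a character vector of valid SMILES.
#' @return data.frame with columns `mw`, `logp`, `sa`, `qed`.
#' @export
mol_properties <- function(x) {
  m <- if (inherits(x, "molecule_set")) {
    ms_features(x, "props")$props
  } else {
    backend_mol_info(as.character(x), "props")$props
  }
  as.data.frame(m)
}

#' Descriptor embedding of a molecule set
#'
#' A 12-dimensional physicochemical descriptor vector per molecule (MW,
#' logP, SA, QED, TPSA, H-bond acceptors/donors, rotatable bonds,
#' aromatic rings, rings, fraction sp3 carbons, heavy atoms). This is the
#' default pluggable embedding for the Fréchet-distance machinery; it is
#' a documented stand-in and its absolute Fréchet distances are not
#' comparable to distances computed over neural-network activations.
#'
#' @param x a `molecule_set` or a character vector of valid SMILES.
#' @return numeric matrix, one row per molecule.
#' @export
descriptor_embedding <- function(x) {
  if (inherits(x, "molecule_set")) {
    ms_features(x, "descriptors")$descriptors
  } else {
    backend_mol_info(as.character(x), "descriptors")$descriptors
  }
}
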