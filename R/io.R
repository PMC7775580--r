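# Plain-text molecule I/O: one-SMILES-per-line files and delimited
# tables with SMILES and SPLIT columns.

#' Read and write SMILES files
#'
#' `read_smiles_file()` reads a UTF-8 text file with one SMILES per line
#' (no header, blank lines skipped) into a `molecule_set`.
#' `write_smiles_file()` writes one SMILES per line; by default the
#' source spelling is kept.
#'
#' @param path file path.
#' @param provenance label attached to the returned set (defaults to the
#'   file name).
#' @param ms a `molecule_set`.
#' @param canonical write canonical SMILES instead of the source spelling
#'   (invalid entries are then dropped).
#' @return `read_smiles_file()` a `molecule_set`; `write_smiles_file()`
#'   the path, invisibly.
#' @export
read_smiles_file <- function(path, provenance = basename(path)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  molecule_set(lines[nzchar(lines)], provenance = provenance)
}

#' @rdname read_smiles_file
#' @export
write_smiles_file <- function(ms, path, canonical = FALSE) {
  stopifnot(inherits(ms, "molecule_set"))
  out <- if (canonical) valid_smiles(ms) else ms$source_smiles
  writeLines(out, path)
  invisible(path)
}

#' Read and write SMILES+SPLIT tables
#'
#' A delimited table (comma or tab, inferred from the extension) with at
#' least a `SMILES` column and optionally a `SPLIT` column taking values
#' `train`, `test`, `test_scaffolds`. `read_split_table()` returns a
#' named list of `molecule_set`s, one per split (a single unnamed set
#' under `"all"` when SPLIT is absent).
#'
#' @param path file path (`.csv` or `.tsv`/`.txt`).
#' @param splits a named list of `molecule_set`s to write.
#' @return `read_split_table()` a named list of `molecule_set`s.
#' @export
read_split_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df) <- toupper(names(df))
  if (!"SMILES" %in% names(df)) stop("table has no SMILES column: ", path)
  if (!"SPLIT" %in% names(df)) {
    return(list(all = molecule_set(df$SMILES, provenance = basename(path))))
  }
  known <- c("train", "test", "test_scaffolds")
  bad <- setdiff(unique(df$SPLIT), known)
  if (length(bad) > 0L) {
    stop("unknown SPLIT values: ", paste(bad, collapse = ", "))
  }
  out <- lapply(intersect(known, unique(df$SPLIT)), function(s) {
    molecule_set(df$SMILES[df$SPLIT == s], provenance = s)
  })
  stats::setNames(out, intersect(known, unique(df$SPLIT)))
}

#' @rdname read_split_table
#' @export
write_split_table <- function(splits, path) {
  stopifnot(is.list(splits), length(names(splits)) == length(splits))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rows <- do.call(rbind, lapply(names(splits), function(s) {
    data.frame(SMILES = splits[[s]]$source_smiles, SPLIT = s,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# SMARTS pattern lists: one pattern per line, '#' comments allowed at
# line start or after whitespace ('#' inside a pattern is SMARTS syntax:
# triple bond, atomic number)
read_smarts_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(lines, function(l) sub("\\s.*$", "", l), character(1),
         USE.NAMES = FALSE)
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state;
# the RNG kind is pinned so results do not depend on the calling context
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}
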