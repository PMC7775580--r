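# SMILES tokenizer for the sequence baselines. Multi-character tokens —
# two-letter halogens (Cl, Br), bracket atoms ([nH], [C@@H], ...) and
# two-digit ring closures (%NN) — are kept whole so that samplers never
# emit half an atom symbol.

#' @rdname tokenize
#' @export
BEGIN_TOKEN <- "<bos>"

#' @rdname tokenize
#' @export
END_TOKEN <- "<eos>"

.token_regex <- "\\[[^][]*\\]|Cl|Br|%[0-9]{2}|."

#' Tokenize and detokenize SMILES strings
#'
#' `tokenize()` splits a SMILES string into atom/bond/ring-closure tokens
#' and frames them with distinguished begin/end markers; `detokenize()`
#' strips the markers and concatenates the rest, reproducing the source
#' string byte-exactly.
#'
#' @param smiles a single SMILES string.
#' @param tokens a character vector of tokens, optionally framed by
#'   `BEGIN_TOKEN` / `END_TOKEN`.
#' @return `tokenize()` a character vector
#'   `c(BEGIN_TOKEN, ..., END_TOKEN)`; `detokenize()` a string.
#' @examples
#' tokenize("CCl")          # "<bos>" "C" "Cl" "<eos>"
#' detokenize(tokenize("c1ccccc1"))
#' @export
tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) return(c(BEGIN_TOKEN, END_TOKEN))
  m <- gregexpr(.token_regex, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (any(toks == "[")) {
    stop("unterminated bracket atom in SMILES: ", smiles)
  }
  if (any(toks == "%")) {
    stop("dangling '%' ring closure in SMILES: ", smiles)
  }
  if (!identical(paste(toks, collapse = ""), smiles)) {
    stop("tokenization does not round-trip for: ", smiles)
  }
  c(BEGIN_TOKEN, toks, END_TOKEN)
}

#' @rdname tokenize
#' @export
detokenize <- function(tokens) {
  stopifnot(is.character(tokens))
  paste(tokens[!(tokens %in% c(BEGIN_TOKEN, END_TOKEN))], collapse = "")
}
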