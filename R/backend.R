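# Bridge to the RDKit-based chemistry helper shipped in inst/python/.
# Every call is batched over a vector of SMILES; requests and responses
# are JSON files exchanged with a short-lived python process.

backend_script <- function() {
  system.file("python", "chem_tool.py", package = "molbench", mustWork = TRUE)
}

backend_python <- function() {
  getOption("molbench.python", Sys.getenv("MOLBENCH_PYTHON", "python"))
}

chem_backend <- function(op, payload) {
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(c(list(op = jsonlite::unbox(op)), payload), req,
                       auto_unbox = FALSE, digits = NA, null = "null")
  err <- tempfile(fileext = ".log")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(
    system2(backend_python(), shQuote(c(backend_script(), req, resp)),
            stdout = FALSE, stderr = err)
  )
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("chemistry backend failed (op=", op, "):\n", msg, call. = FALSE)
  }
  jsonlite::read_json(resp, simplifyVector = FALSE)
}

# character vector (possibly length 0/1) -> JSON array, never a scalar
as_json_chr <- function(x) lapply(as.character(x), jsonlite::unbox)

backend_parse <- function(smiles) {
  if (length(smiles) == 0L) {
    return(list(valid = logical(0), canonical = character(0)))
  }
  out <- chem_backend("parse", list(smiles = as_json_chr(smiles)))
  list(
    valid = vapply(out$valid, isTRUE, logical(1)),
    canonical = vapply(out$canonical,
                       function(x) if (is.null(x)) NA_character_ else x,
                       character(1))
  )
}

#' @noRd
backend_mol_info <- function(smiles, fields) {
  stopifnot(length(smiles) > 0L)
  out <- chem_backend("mol_info", list(smiles = as_json_chr(smiles),
                                       fields = as_json_chr(fields)))
  res <- list()
  if ("fp" %in% fields) {
    res$fp <- lapply(out$fp, function(v) as.integer(unlist(v)))
  }
  for (f in intersect(c("frags", "frags_labeled"), fields)) {
    res[[f]] <- lapply(out[[f]], function(v) as.character(unlist(v)))
  }
  if ("scaffold" %in% fields) {
    res$scaffold <- vapply(out$scaffold, as.character, character(1))
  }
  if ("props" %in% fields) {
    m <- do.call(rbind, lapply(out$props, as.numeric))
    colnames(m) <- c("mw", "logp", "sa", "qed")
    res$props <- m
  }
  if ("descriptors" %in% fields) {
    res$descriptors <- do.call(rbind, lapply(out$descriptors, as.numeric))
  }
  res
}

backend_filters <- function(smiles, cfg) {
  payload <- list(
    smiles = as_json_chr(smiles),
    allowed_elements = as_json_chr(cfg$allowed_elements),
    max_ring_size = jsonlite::unbox(as.integer(cfg$max_ring_size)),
    forbid_charges = jsonlite::unbox(isTRUE(cfg$forbid_charges)),
    mcf = as_json_chr(cfg$mcf),
    pains = as_json_chr(cfg$pains)
  )
  if (!is.null(cfg$mw_range)) {
    payload$mw_range <- lapply(as.numeric(cfg$mw_range), jsonlite::unbox)
  }
  if (!is.null(cfg$max_rotatable)) {
    payload$max_rotatable <- jsonlite::unbox(as.integer(cfg$max_rotatable))
  }
  if (!is.null(cfg$max_xlogp)) {
    payload$max_xlogp <- jsonlite::unbox(as.numeric(cfg$max_xlogp))
  }
  out <- chem_backend("filters", payload)
  lapply(out$reasons, function(v) as.character(unlist(v)))
}

backend_assemble <- function(frag_sets, seeds, attempts = 10L) {
  stopifnot(length(frag_sets) == length(seeds))
  jobs <- Map(function(fr, sd) {
    list(frags = as_json_chr(fr), seed = jsonlite::unbox(as.integer(sd)))
  }, frag_sets, seeds)
  out <- chem_backend("assemble",
                      list(jobs = jobs,
                           attempts = jsonlite::unbox(as.integer(attempts))))
  vapply(out$smiles, function(x) if (is.null(x)) NA_character_ else x,
         character(1))
}
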