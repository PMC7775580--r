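# Full-protocol orchestration: fit a baseline on the train split, sample
# with several seeds, evaluate each sample set against the test (and
# scaffold-test) splits, and aggregate per-metric mean +/- SD.

#' Run the distribution-learning benchmark for one baseline model
#'
#' For each seed: fit the selected baseline on `train`, draw `n_samples`
#' molecules, and evaluate them against `test` (and `test_scaffolds`
#' when supplied). Replicates differ only in the sampling (and, for the
#' HMM, initialization) seed, mirroring the protocol of evaluating a
#' model over several independent initializations. All randomness is
#' derived from the seeds, so identical configurations give identical
#' reports.
#'
#' @param train,test reference `molecule_set`s.
#' @param model `"combinatorial"`, `"ngram"` or `"hmm"`.
#' @param n_samples molecules to generate per seed (the full protocol
#'   uses 30,000; desk-scale runs use less).
#' @param seeds integer vector of distinct seeds (3 by default).
#' @param test_scaffolds optional scaffold-held-out `molecule_set`.
#' @param cfg a [filter_config()].
#' @param model_args named list of extra arguments for the model fit
#'   (e.g. `list(n = 3)` for the n-gram order or `list(K = 8)` for HMM
#'   states).
#' @param embedder embedding for the Fréchet distance.
#' @param quiet suppress stage log messages.
#' @return a `benchmark_result`: `reports` (per-seed `metric_report`s),
#'   `summary` (data.frame metric/mean/sd) and the resolved
#'   configuration.
#' @export
run_benchmark <- function(train, test, model = c("combinatorial", "ngram",
                                                 "hmm"),
                          n_samples = 30000L, seeds = c(1L, 2L, 3L),
                          test_scaffolds = NULL, cfg = filter_config(),
                          model_args = list(),
                          embedder = descriptor_embedding,
                          quiet = FALSE) {
  model <- match.arg(model)
  stopifnot(length(seeds) >= 1L, !anyDuplicated(seeds), n_samples >= 1L)
  say <- function(...) if (!quiet) message("run_benchmark: ", ...)

  reports <- list()
  for (sd in seeds) {
    rep_i <- tryCatch({
      say("seed ", sd, ": fitting ", model, " on ",
          n_valid(train), " molecules")
      G <- switch(model,
        combinatorial = {
          lib <- do.call(combinatorial_fit,
                         c(list(corpus = train), model_args))
          combinatorial_sample_many(lib, n_samples, seed = sd)
        },
        ngram = {
          m <- do.call(ngram_fit, c(list(corpus = train), model_args))
          molecule_set(ngram_sample_many(m, n_samples, seed = sd),
                       provenance = sprintf("ngram(seed=%d)", sd))
        },
        hmm = {
          m <- do.call(hmm_fit,
                       c(list(corpus = train, seed = sd), model_args))
          molecule_set(hmm_sample_many(m, n_samples, seed = sd),
                       provenance = sprintf("hmm(seed=%d)", sd))
        })
      say("seed ", sd, ": ", sum(G$valid), "/", length(G),
          " valid samples; evaluating")
      evaluate(G, train, test, test_scaffolds = test_scaffolds,
               cfg = cfg, embedder = embedder)
    }, error = function(e) {
      warning("seed ", sd, " failed: ", conditionMessage(e))
      NULL
    })
    reports[[as.character(sd)]] <- rep_i
  }
  ok <- !vapply(reports, is.null, logical(1))
  if (!any(ok)) stop("run_benchmark: every seed failed")

  flat <- do.call(rbind, lapply(reports[ok], flatten_report))
  summary <- data.frame(
    metric = colnames(flat),
    mean = apply(flat, 2L, mean),
    sd = if (nrow(flat) > 1L) apply(flat, 2L, stats::sd) else 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(model = model, reports = reports, summary = summary,
                 config = list(model = model, n_samples = n_samples,
                               seeds = seeds, model_args = model_args)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s over %d seed(s)\n", x$model,
              length(x$config$seeds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f ± %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write and read benchmark reports
#'
#' Serializes the per-metric mean/SD summary as JSON, CSV or a markdown
#' table. Columns follow the conventional benchmark report order; a
#' metric that was not computed (e.g. the TestSF block when no
#' scaffold-test split was supplied) is absent from the report, never
#' written as zero. JSON and CSV reports round-trip through
#' `read_report()`.
#'
#' @param result a `benchmark_result` (or the `summary` data.frame of
#'   one).
#' @param path output file.
#' @param format `"json"`, `"csv"` or `"markdown"` (default from the
#'   file extension).
#' @return `path`, invisibly; `read_report()` returns the summary
#'   data.frame.
#' @export
write_report <- function(result, path,
                         format = c("auto", "json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv", md = "markdown",
                     stop("cannot infer report format from: ", path))
  }
  s <- if (inherits(result, "benchmark_result")) result$summary else result
  model <- if (inherits(result, "benchmark_result")) result$model else "model"
  switch(format,
    json = jsonlite::write_json(
      list(model = model,
           metrics = stats::setNames(
             lapply(seq_len(nrow(s)),
                    function(i) list(mean = s$mean[i], sd = s$sd[i])),
             s$metric)),
      path, auto_unbox = TRUE, digits = NA),
    csv = utils::write.csv(cbind(model = model, s), path, row.names = FALSE),
    markdown = {
      lines <- c(
        paste("| Model |", paste(s$metric, collapse = " | "), "|"),
        paste0("|", paste(rep("---", nrow(s) + 1L), collapse = "|"), "|"),
        paste("|", model, "|",
              paste(sprintf("%.4f ± %.4f", s$mean, s$sd),
                    collapse = " | "), "|"))
      writeLines(lines, path)
    })
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path)
    data.frame(metric = names(j$metrics),
               mean = vapply(j$metrics, function(m) as.numeric(m$mean),
                             numeric(1)),
               sd = vapply(j$metrics, function(m) as.numeric(m$sd),
                           numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    df[, c("metric", "mean", "sd")]
  } else {
    stop("read_report supports json and csv")
  }
}
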