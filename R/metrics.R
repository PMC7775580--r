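# Distribution-learning evaluation metrics: validity, uniqueness,
# novelty, filter compliance, fragment/scaffold cosine similarity,
# nearest-neighbor Tanimoto similarity, internal diversity, Fréchet
# distance over embedding statistics, and property-distribution
# Wasserstein-1 distances.

#' Fraction of valid molecules
#'
#' @param G a `molecule_set` of generated molecules.
#' @return fraction of entries that parse to a chemically valid
#'   structure.
#' @export
valid_fraction <- function(G) {
  stopifnot(inherits(G, "molecule_set"))
  if (length(G) == 0L) stop("valid_fraction: empty molecule set")
  mean(G$valid)
}

#' Uniqueness among the first k valid molecules
#'
#' Takes the first `k` valid molecules in generation order (all valid
#' molecules if fewer than `k`) and returns the fraction of distinct
#' canonical SMILES among them.
#'
#' @param G a `molecule_set`.
#' @param k window size (1,000 and 10,000 are the conventional choices).
#' @return fraction in (0, 1\].
#' @export
unique_at_k <- function(G, k) {
  stopifnot(inherits(G, "molecule_set"), k >= 1)
  smi <- valid_smiles(G)
  if (length(smi) == 0L) stop("unique_at_k: no valid molecules")
  smi <- smi[seq_len(min(length(smi), k))]
  length(unique(smi)) / length(smi)
}

#' Novelty with respect to a training set
#'
#' Fraction of the (valid) generated molecules whose canonical SMILES is
#' absent from the training set. Duplicate generated molecules are
#' counted per draw.
#'
#' @param G generated `molecule_set`.
#' @param train training `molecule_set`.
#' @return fraction in \[0, 1\].
#' @export
novelty <- function(G, train) {
  stopifnot(inherits(G, "molecule_set"), inherits(train, "molecule_set"))
  g <- valid_smiles(G)
  if (length(g) == 0L) stop("novelty: no valid generated molecules")
  ref <- unique(valid_smiles(train))
  mean(!(g %in% ref))
}

#' Fraction of generated molecules passing the dataset filters
#'
#' @param G generated `molecule_set`.
#' @param cfg a [filter_config()].
#' @return fraction of valid molecules of `G` passing every filter rule.
#' @export
filters_fraction <- function(G, cfg = filter_config()) {
  stopifnot(inherits(G, "molecule_set"))
  g <- valid_smiles(G)
  if (length(g) == 0L) stop("filters_fraction: no valid molecules")
  mean(passes_filters(g, cfg)$pass)
}

#' Substructure occurrence counts of a molecule set
#'
#' Counts how often each substructure key occurs across the set:
#' per-molecule BRICS fragment multiplicities (`kind = "fragment"`) or
#' one count per molecule for its Bemis-Murcko scaffold
#' (`kind = "scaffold"`; acyclic molecules count under the empty key).
#'
#' @param A a `molecule_set` (valid molecules are counted).
#' @param kind `"fragment"` or `"scaffold"`.
#' @return a `substructure_counts`: named integer vector of counts with
#'   attribute `kind`.
#' @export
substructure_counts <- function(A, kind = c("fragment", "scaffold")) {
  kind <- match.arg(kind)
  keys <- if (kind == "fragment") {
    unlist(brics_fragments(A), use.names = FALSE)
  } else {
    bm_scaffold(A)
  }
  tab <- table(keys)
  structure(stats::setNames(as.integer(tab), names(tab)), kind = kind,
            class = "substructure_counts")
}

#' Cosine similarity of two substructure count vectors
#'
#' The fragment (Frag) and scaffold (Scaff) similarity metric: cosine of
#' the two count vectors over the union of their key spaces. 0 if either
#' vector is empty or all-zero.
#'
#' @param cG,cR `substructure_counts` of the same kind.
#' @return similarity in \[0, 1\].
#' @export
cosine_count_similarity <- function(cG, cR) {
  kG <- attr(cG, "kind"); kR <- attr(cR, "kind")
  if (!is.null(kG) && !is.null(kR) && !identical(kG, kR)) {
    stop("substructure kinds differ: ", kG, " vs ", kR)
  }
  keys <- union(names(cG), names(cR))
  if (length(keys) == 0L) return(0)
  # positional matching: the empty-scaffold key "" cannot be looked up
  # by name in R
  g <- numeric(length(keys))
  g[match(names(cG), keys)] <- as.numeric(cG)
  r <- numeric(length(keys))
  r[match(names(cR), keys)] <- as.numeric(cR)
  den <- sqrt(sum(g^2)) * sqrt(sum(r^2))
  if (den == 0) return(0)
  sum(g * r) / den
}

#' Similarity to the nearest neighbor (SNN)
#'
#' Average over generated molecules of the maximum Tanimoto similarity
#' (Morgan fingerprints, radius 2, 1024 bits) to any reference molecule.
#' Not symmetric in its arguments.
#'
#' @param G generated `molecule_set`.
#' @param R reference `molecule_set`.
#' @return similarity in \[0, 1\].
#' @export
snn <- function(G, R) {
  fg <- ms_features(G, "fp")$fp
  fr <- ms_features(R, "fp")$fp
  if (length(fg) == 0L || length(fr) == 0L) stop("snn: empty input")
  sim <- tanimoto_matrix(fg, fr)
  mean(apply(sim, 1L, max))
}

#' Internal diversity of a generated set
#'
#' `1 - (mean of T(m1, m2)^p over all ordered pairs)^(1/p)`, the double
#' sum running over all ordered pairs including each molecule with
#' itself. A singleton set (or any set of copies of one molecule)
#' therefore has diversity 0.
#'
#' @param G a `molecule_set`.
#' @param p power, 1 or 2.
#' @return diversity in \[0, 1\].
#' @export
internal_diversity <- function(G, p = 1L) {
  stopifnot(p %in% c(1L, 2L))
  fg <- ms_features(G, "fp")$fp
  if (length(fg) == 0L) stop("internal_diversity: empty input")
  sim <- tanimoto_matrix(fg, fg)
  1 - mean(sim^p)^(1 / p)
}

#' Mean and covariance of a molecule-set embedding
#'
#' @param A a `molecule_set` (at least 2 valid molecules) or a numeric
#'   matrix of precomputed embedding vectors (one row per molecule, e.g.
#'   externally computed neural-network activations).
#' @param embedder function mapping a `molecule_set` to an embedding
#'   matrix; defaults to [descriptor_embedding()].
#' @return an `embedding_stats`: list with mean vector `mu` and sample
#'   covariance matrix `sigma` (denominator n-1).
#' @export
embedding_stats <- function(A, embedder = descriptor_embedding) {
  X <- if (is.matrix(A)) A else embedder(A)
  if (!is.numeric(X) || !is.matrix(X)) stop("embedding must be a numeric matrix")
  if (nrow(X) < 2L) stop("embedding_stats: need at least 2 molecules")
  structure(list(mu = colMeans(X), sigma = stats::cov(X)),
            class = "embedding_stats")
}

# symmetric PSD matrix square root via eigendecomposition; eigenvalues
# below -tol error out, small negatives are clipped to 0
sqrtm_psd <- function(S, tol = 1e-3) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (min(e$values) < -tol * scale) {
    stop("matrix square root undefined: eigenvalue ",
         format(min(e$values)), " beyond tolerance (covariance pathology)")
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two Gaussian embedding summaries
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, the
#' 2-Wasserstein distance between the Gaussians fitted to two embedded
#' molecule sets. With neural-network activation embeddings this is the
#' FCD; with the default descriptor embedding it is the same machinery
#' on a documented stand-in (absolute values are not comparable across
#' embeddings).
#'
#' @param a,b `embedding_stats` of matching dimension.
#' @return non-negative distance (values negative within 1e-6 from
#'   rounding are clipped to 0).
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "embedding_stats"), inherits(b, "embedding_stats"))
  if (length(a$mu) != length(b$mu)) stop("embedding dimensions differ")
  sa <- sqrtm_psd(a$sigma)
  # Tr[(Sa Sb)^(1/2)] computed via the congruent symmetric form
  # (sqrt(Sa) Sb sqrt(Sa))^(1/2), which shares its eigenvalues
  m <- sa %*% b$sigma %*% sa
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-3 * scale) {
    stop("Frechet distance: covariance product has significantly ",
         "negative spectrum (covariance pathology)")
  }
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  d <- sum((a$mu - b$mu)^2) +
    sum(diag(a$sigma)) + sum(diag(b$sigma)) - 2 * tr_sqrt
  if (d < 0 && d > -1e-6) d <- 0
  max(d, 0)
}

#' Wasserstein-1 distance between two empirical 1-D distributions
#'
#' Computed as the integral of the absolute difference of the two
#' empirical CDFs. Symmetric; 0 iff the empirical distributions
#' coincide.
#'
#' @param x,y numeric samples (non-empty).
#' @return non-negative distance.
#' @export
wasserstein1 <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("wasserstein1: empty sample")
  pts <- sort(unique(c(x, y)))
  if (length(pts) == 1L) return(0)
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  k <- length(pts)
  sum(abs(Fx[-k] - Fy[-k]) * diff(pts))
}

#' Evaluate a generated set against reference sets
#'
#' Computes the full metric battery for a generated set `G`: validity,
#' Unique@1k/Unique@10k, filter compliance, novelty vs `train`, internal
#' diversity, and — against `test` and (when supplied) `test_scaffolds`
#' — fragment and scaffold cosine similarity, SNN, and the Fréchet
#' distance over the chosen embedding. Property (MW/logP/SA/QED)
#' Wasserstein-1 distances are computed against `test`. All metrics
#' except validity are computed on the valid molecules of `G` only.
#'
#' @param G generated `molecule_set`.
#' @param train,test reference `molecule_set`s.
#' @param test_scaffolds optional scaffold-held-out `molecule_set`.
#' @param cfg a [filter_config()].
#' @param embedder embedding function for the Fréchet distance; see
#'   [embedding_stats()].
#' @param activations_gen,activations_ref optional precomputed embedding
#'   matrices (e.g. neural-network activations) for `G` and `test`; when
#'   given they replace `embedder` for the Test-column Fréchet distance.
#' @return a `metric_report`: named list of metric values.
#' @export
evaluate <- function(G, train, test, test_scaffolds = NULL,
                     cfg = filter_config(),
                     embedder = descriptor_embedding,
                     activations_gen = NULL, activations_ref = NULL) {
  stopifnot(inherits(G, "molecule_set"))
  if (length(G) == 0L) stop("evaluate: empty generated set")
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("metric '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  Gv <- ms_subset(G, which(G$valid))

  rep <- list()
  rep$valid <- wrap("valid", valid_fraction(G))
  rep$unique_at_1k <- wrap("unique@1k", unique_at_k(G, 1000L))
  rep$unique_at_10k <- wrap("unique@10k", unique_at_k(G, 10000L))
  rep$filters <- wrap("filters", filters_fraction(G, cfg))
  rep$novelty <- wrap("novelty", novelty(G, train))
  rep$intdiv1 <- wrap("intdiv1", internal_diversity(Gv, 1L))
  rep$intdiv2 <- wrap("intdiv2", internal_diversity(Gv, 2L))

  # standardize descriptor embeddings by the reference spread so no
  # single descriptor (e.g. molecular weight) dominates the distance
  emb_pair <- function(ref_ms) {
    Xr <- embedder(ref_ms)
    Xg <- embedder(Gv)
    mu <- colMeans(Xr)
    sd <- apply(Xr, 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(g = sweep(sweep(Xg, 2L, mu), 2L, sd, "/"),
         r = sweep(sweep(Xr, 2L, mu), 2L, sd, "/"))
  }
  against <- function(ref_ms, suffix) {
    out <- list()
    out[[paste0("frag_", suffix)]] <- wrap(paste0("frag/", suffix),
      cosine_count_similarity(substructure_counts(Gv, "fragment"),
                              substructure_counts(ref_ms, "fragment")))
    out[[paste0("scaff_", suffix)]] <- wrap(paste0("scaff/", suffix),
      cosine_count_similarity(substructure_counts(Gv, "scaffold"),
                              substructure_counts(ref_ms, "scaffold")))
    out[[paste0("snn_", suffix)]] <- wrap(paste0("snn/", suffix),
      snn(Gv, ref_ms))
    out[[paste0("fcd_", suffix)]] <- wrap(paste0("fcd/", suffix), {
      if (suffix == "test" && !is.null(activations_gen) &&
          !is.null(activations_ref)) {
        frechet_distance(embedding_stats(as.matrix(activations_gen)),
                         embedding_stats(as.matrix(activations_ref)))
      } else {
        ep <- emb_pair(ref_ms)
        frechet_distance(embedding_stats(ep$g), embedding_stats(ep$r))
      }
    })
    out
  }
  rep <- c(rep, against(test, "test"))
  if (!is.null(test_scaffolds)) {
    rep <- c(rep, against(test_scaffolds, "testsf"))
  }

  rep$property_w1 <- wrap("property_w1", {
    pg <- mol_properties(Gv)
    pr <- mol_properties(test)
    vapply(c("mw", "logp", "sa", "qed"),
           function(p) wasserstein1(pg[[p]], pr[[p]]), numeric(1))
  })

  check_metric_bounds(rep)
  structure(rep, class = "metric_report")
}

# every bounded metric must lie within its limits
check_metric_bounds <- function(rep) {
  unitb <- c("valid", "unique_at_1k", "unique_at_10k", "filters", "novelty",
             "intdiv1", "intdiv2",
             grep("^(frag|scaff|snn)_", names(rep), value = TRUE))
  for (f in intersect(unitb, names(rep))) {
    v <- rep[[f]]
    if (!is.finite(v) || v < -1e-12 || v > 1 + 1e-12) {
      stop("metric ", f, " out of [0,1]: ", v)
    }
  }
  for (f in grep("^fcd_", names(rep), value = TRUE)) {
    if (!is.finite(rep[[f]]) || rep[[f]] < 0) {
      stop("metric ", f, " negative: ", rep[[f]])
    }
  }
  if (!is.null(rep$property_w1) && any(rep$property_w1 < 0)) {
    stop("negative property W1 distance")
  }
  invisible(rep)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  flat <- flatten_report(x)
  for (nm in names(flat)) cat(sprintf("  %-14s %.6g\n", nm, flat[[nm]]))
  invisible(x)
}

# named numeric vector with conventional benchmark column names
flatten_report <- function(rep) {
  cols <- c(valid = "Valid", unique_at_1k = "Unique@1k",
            unique_at_10k = "Unique@10k", filters = "Filters",
            novelty = "Novelty", intdiv1 = "IntDiv1", intdiv2 = "IntDiv2",
            fcd_test = "FCD/Test", fcd_testsf = "FCD/TestSF",
            snn_test = "SNN/Test", snn_testsf = "SNN/TestSF",
            frag_test = "Frag/Test", frag_testsf = "Frag/TestSF",
            scaff_test = "Scaf/Test", scaff_testsf = "Scaf/TestSF")
  out <- numeric(0)
  for (f in names(cols)) {
    if (!is.null(rep[[f]])) out[cols[[f]]] <- rep[[f]]
  }
  if (!is.null(rep$property_w1)) {
    w1names <- c(mw = "W1/MW", logp = "W1/LogP", sa = "W1/SA", qed = "W1/QED")
    for (p in names(w1names)) out[w1names[[p]]] <- rep$property_w1[[p]]
  }
  out
}
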