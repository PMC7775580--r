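# Synthetic molecule-set generator. Fixture molecules are built by
# decorating a pool of ring scaffolds (drug-like mono- and bicyclics,
# rings of at most 8 atoms, elements C/N/S/O/F/Cl/Br/H, uncharged) with
# small substituents, so scaffold splits, fragment statistics and filter
# rules are all exercisable on sets that share substructure the way a
# screening collection does.

# Scaffold templates. "{k}" marks a carbon substitution site (full
# substituent pool), "{nk}" a ring-nitrogen site (carbon-attached
# substituents only, so no N-halogen or N-O bonds arise).
.fixture_templates <- c(
  "c1c{1}cc{2}cc1",                    # benzene
  "c1ccnc{1}c1",                       # pyridine
  "c1ncnc{1}c1",                       # pyrimidine
  "c1cnc{1}cn1",                       # pyrazine
  "c1cc{1}oc1",                        # furan
  "c1cc{1}sc1",                        # thiophene
  "c1c{1}c[nH]c1",                     # pyrrole
  "c1c[nH]c{1}n1",                     # imidazole
  "c1oc{1}nc1",                        # oxazole
  "c1csc{1}n1",                        # thiazole
  "c1ccc2cc{1}ccc2c1",                 # naphthalene
  "c1ccc2nc{1}ccc2c1",                 # quinoline
  "c1ccc2[nH]cc{1}c2c1",               # indole
  "c1ccc2occ{1}c2c1",                  # benzofuran
  "c1ccc2scc{1}c2c1",                  # benzothiophene
  "c1ccc2[nH]cnc2c1",                  # benzimidazole
  "C1C{1}C1",                          # cyclopropane
  "C1C{1}CC1",                         # cyclobutane
  "C1CC{1}CC1",                        # cyclopentane
  "C1CC{1}CC{2}C1",                    # cyclohexane
  "C1CCC{1}CCC1",                      # cycloheptane
  "C1CCCC{1}CCC1",                     # cyclooctane
  "C1CCN{n1}CC1",                      # piperidine
  "C1CN{n1}CCN1",                      # piperazine
  "O1CCN{n1}CC1",                      # morpholine
  "C1CCN{n1}C1",                       # pyrrolidine
  "C1CC{1}CO1",                        # tetrahydrofuran
  "C1CC{1}OCC1",                       # tetrahydropyran
  "O=C1CC{1}CCC1",                     # cyclohexanone
  "O=C1N{n1}CC{2}C1",                  # 2-pyrrolidinone
  "O=c1ccc{1}c[nH]1",                  # 2-pyridone
  "c1ccc(-c2ccc{1}cc2)cc1",            # biphenyl
  "c1ccc(Cc2ccc{1}cc2)cc1",            # diphenylmethane
  "C1CCN(Cc2ccc{1}cc2)CC1",            # benzylpiperidine
  "c1ccc(N2CCN{n1}CC2)cc1",            # phenylpiperazine
  "C1Cc2ccccc2C1",                     # indane
  "C1CCc2ccccc2C1",                    # tetralin
  "C1Cc2ccccc2OC1"                     # chromane
)

# substituents, by attaching atom: carbon-attached everywhere, hetero- or
# halogen-attached only at carbon sites
.subs_carbon <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO",
                  "C(=O)N", "C(=O)NC", "C(=O)OC", "C#N", "C(F)(F)F",
                  "CN(C)C", "CNC(=O)C")
.subs_hetero <- c("F", "Cl", "Br", "OC", "OCC", "N", "NC", "N(C)C",
                  "SC", "S(C)(=O)=O")

.decorate <- function(template, rng_sub_prob = 0.65) {
  sites <- regmatches(template,
                      gregexpr("\\{n?[0-9]\\}", template))[[1]]
  out <- template
  for (s in sites) {
    pool <- if (grepl("n", s, fixed = TRUE)) {
      .subs_carbon
    } else {
      c(.subs_carbon, .subs_hetero)
    }
    rep_with <- if (stats::runif(1) < rng_sub_prob) {
      paste0("(", sample(pool, 1L), ")")
    } else {
      ""
    }
    out <- sub(s, rep_with, out, fixed = TRUE)
  }
  out
}

#' Generate a synthetic molecule set
#'
#' Emits `n` valid, uncharged SMILES over elements C/N/S/O/F/Cl/Br/H with
#' rings of at most 8 atoms, by decorating up to `scaffold_pool` distinct
#' ring scaffolds with varied substituents. The output is deterministic
#' given `seed`, every emitted molecule passes the default
#' dataset-construction filters, and the number of distinct Bemis-Murcko
#' scaffolds never exceeds `scaffold_pool` — so the sets exercise
#' scaffold splitting and fragment statistics realistically.
#'
#' @param n number of molecules to emit (duplicates possible; multiset).
#' @param seed integer RNG seed.
#' @param scaffold_pool number of distinct scaffolds to draw from (capped
#'   at the size of the built-in template library).
#' @return a `molecule_set` of `n` valid molecules.
#' @export
make_fixture_set <- function(n, seed = 1L, scaffold_pool = 30L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  pool_n <- min(as.integer(scaffold_pool), length(.fixture_templates))
  smiles <- with_seed(seed, {
    pool <- .fixture_templates[sample.int(length(.fixture_templates), pool_n)]
    vapply(seq_len(n),
           function(i) .decorate(pool[[sample.int(pool_n, 1L)]]),
           character(1))
  })
  p <- backend_parse(smiles)
  if (!all(p$valid)) {
    stop("internal error: fixture generator emitted invalid SMILES: ",
         paste(utils::head(smiles[!p$valid], 3L), collapse = " "))
  }
  new_molecule_set(smiles, p$valid, p$canonical,
                   provenance = sprintf("fixture(n=%d,seed=%d)", n, seed))
}
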