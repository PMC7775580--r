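---
title: "Benchmarking distribution-learning molecular generators with molbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking distribution-learning molecular generators with molbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A distribution-learning generative model is trained on a collection of
molecules and asked to sample new ones that look like draws from the
same chemical distribution. Comparing such models is harder than
comparing predictive models: there is no single held-out loss, and a
model can fail in several orthogonal ways — emitting syntactically or
chemically broken SMILES, collapsing onto a few molecules, copying the
training set verbatim, drifting into reactive or promiscuous chemotypes,
or matching molecules individually while missing the shape of the
distribution. molbench implements the standard metric battery that
probes each failure mode separately, the dataset-construction pipeline
that defines a clean training distribution with a scaffold-held-out test
set, and three non-neural baseline generators that calibrate the scale
of every metric.

All molecules are handled as SMILES strings; molecular identity
throughout the package is the canonical SMILES produced by the RDKit
canonicalisation in the bundled helper process, and validity means the
string survives RDKit's sanitisation (atom valences, aromatic-ring
consistency). Stereochemistry is kept exactly as the toolkit parses it —
no stripping — so two stereoisomers are different molecules for
uniqueness and novelty.

## Metrics

Let `G` be the generated set (all metrics except validity are computed
on its valid molecules only, duplicates retained per draw) and `R` a
reference set.

* **Valid** — fraction of generated strings parsing to a valid
  structure.
* **Unique@k** — distinct canonical SMILES among the first `k` valid
  molecules in generation order (all of them if fewer than `k`).
* **Novelty** — fraction of valid generated draws whose canonical
  SMILES does not occur in the training set. Duplicate draws count per
  draw: the metric reads "fraction of the generated molecules", which
  counts draws, not distinct structures.
* **Filters** — fraction of valid generated molecules passing the same
  structural filters used to build the dataset (below).
* **Frag / Scaff** — cosine similarity between substructure count
  vectors: BRICS fragment multiplicities, or one count per molecule for
  its Bemis–Murcko scaffold. Fragment keys are canonical SMILES with
  all attachment points collapsed to one generic wildcard, so the same
  chemical fragment cut under different BRICS rules is a single key.
  Acyclic molecules contribute a distinguished empty-scaffold class
  rather than being dropped, so both sides count over the same key
  space. Cosine of count vectors is scale-invariant: duplicating every
  molecule changes nothing.
* **SNN** — mean, over generated molecules, of the Tanimoto similarity
  to the nearest reference molecule on Morgan fingerprints (radius 2,
  1024 bits). Computed brute-force over all pairs via bit-matrix
  products; not symmetric. Tanimoto of two all-zero fingerprints is
  defined as 0 (a 0/0 guard that cannot trigger for valid molecules).
* **IntDiv_p** — `1 - (mean over all ordered pairs of T(m1,m2)^p)^(1/p)`,
  with the double sum including each molecule paired with itself,
  exactly as the formula is conventionally printed. Consequence: a
  singleton set, or any set of copies of one molecule, has diversity
  exactly 0. We follow the printed formula rather than guessing at
  alternatives that exclude the diagonal.
* **Fréchet distance** — `||mu_G - mu_R||^2 +
  Tr(S_G + S_R - 2 (S_G S_R)^(1/2))` over the mean and sample
  covariance (denominator n−1) of a molecule embedding. The embedding
  is pluggable. The default is a 12-dimensional physicochemical
  descriptor vector (MW, logP, SA, QED, TPSA, HBA, HBD, rotatable
  bonds, aromatic rings, rings, fraction Csp3, heavy atoms),
  standardised by the reference set's mean and spread so no descriptor
  dominates. **This default is a documented stand-in**: absolute values
  are *not* comparable to distances computed over neural-network
  activations (the FCD convention). Externally computed activation
  matrices can be supplied to `evaluate()` to obtain those.
* **Property W1** — Wasserstein-1 distance between the empirical
  distributions of MW, Crippen logP, synthetic-accessibility score
  (1 easy – 10 hard) and QED (0–1), generated vs test, computed exactly
  as the integral of the absolute CDF difference.

Identities used as self-checks (and enforced in the test suite): a set
evaluated against itself has novelty 0, Frag = Scaff = SNN = 1, Fréchet
distance 0 and all property distances 0; every bounded metric is
asserted inside its limits on every `evaluate()` call.

## Numerical choices

The matrix square root in the Fréchet distance is computed from the
congruent symmetric form `sqrt(S_G) S_R sqrt(S_G)` via eigendecomposition,
with eigenvalues in `[-tol, 0)` clipped to zero; a spectrum more
negative than the tolerance aborts with a covariance-pathology error
rather than silently returning a complex-valued root. Distances within
`1e-6` below zero are clipped to 0. Sample covariance uses the n−1
denominator, so at least two molecules are required per set.

## Dataset construction and splitting

`filter_config()` / `build_dataset()` apply, in order: validity, no
formally charged atom (charge removal sidesteps tautomer/pH ambiguity),
elements within C/N/S/O/F/Cl/Br/H, no SSSR ring of more than eight
atoms, and no match to the medicinal-chemistry (MCF) or PAINS SMARTS
lists; survivors are deduplicated by canonical SMILES, first occurrence
kept, with a per-rule rejection log. The shipped SMARTS files are
compact stand-in lists (common reactive groups; the classic PAINS
motifs) — any published catalog can be substituted as a plain-text
file, one pattern per line. Optional lead-likeness pre-filters
(molecular-weight window, rotatable-bond cap, logP cap) mirror the kind
of constraints upstream lead-like collections impose; they are off by
default because they describe the source collection, not the filtering
step proper.

`scaffold_split()` holds out whole Bemis–Murcko scaffold classes:
classes are drawn uniformly at random and accumulated until the
molecules they cover reach the target fraction (default 10%), which
guarantees that no held-out scaffold occurs in train or test — the
scaffold-similarity between train and the scaffold test set is
therefore 0 by construction, a useful end-to-end sanity value. Because
whole classes are taken, the achieved fraction can overshoot; an
overshoot beyond 1.5× the target is flagged with a warning and the
closest achievable split is returned. The empty-scaffold (acyclic)
class is treated like any other class. Drawing classes uniformly
(rather than weighted by class size) is one of two defensible readings
of "a random subset of scaffolds"; the split sizes alone cannot
distinguish them, and uniform drawing is the simpler procedure.

## Baseline generators

* **n-gram** (`ngram_fit()`, default order n = 5): token n-gram counts
  over tokenized canonical SMILES with begin padding and an explicit
  end token, sampled sequentially with stupid backoff to the longest
  observed context. The tokenizer keeps two-letter halogens, bracket
  atoms and two-digit ring closures whole, and round-trips
  byte-exactly.
* **HMM** (`hmm_fit()`, defaults K = 16 states, 50 iterations,
  tolerance 1e-3): discrete-emission hidden Markov model trained with
  Baum–Welch using scaled forward–backward recursions (numerically
  equivalent to log-space, cheaper at these sequence lengths).
  Duplicate token sequences are collapsed and weighted. The
  log-likelihood trace is returned; EM guarantees it non-decreasing,
  which the tests assert, and a single-state model provably collapses
  to the corpus unigram distribution, which the tests check against
  the closed form.
* **Combinatorial** (`combinatorial_fit()` /
  `combinatorial_sample_many()`): BRICS-decomposes the corpus keeping
  attachment-point labels, then samples a fragment count from the
  empirical fragments-per-molecule distribution and fragments
  proportional to corpus frequency, joining them sequentially at
  uniformly chosen attachment-point pairs allowed by the BRICS
  compatibility table (with the prescribed bond order). Leftover
  attachment points are hydrogen-capped. Assemblies that fail
  sanitisation are redrawn, so emitted molecules are valid by
  construction — validity is exactly 100%. One caveat: re-decomposing a
  sampled molecule does not always return the original library keys;
  hydrogen capping changes keys at consumed attachment points, and a
  re-cut across a newly formed bond can merge pieces of two library
  fragments. The tests therefore assert that at least 95% of fragment
  occurrences in samples lie in the capping closure of the library.

At desk scale (a few hundred training molecules, 1,000 samples) the
three baselines reproduce the qualitative validity ordering that
motivates them: combinatorial (1.0) > n-gram > HMM, the sequence models
degrading because their limited context cannot track ring closures and
branch balancing.

## The synthetic fixture generator

`make_fixture_set()` builds molecules by decorating a pool of up to 38
drug-like ring scaffolds (aromatic heterocycles, saturated rings, fused
bicyclics, two-ring systems with linkers; all rings ≤ 8 atoms) with
small benign substituents at chemistry-aware sites (ring nitrogens only
accept carbon-attached groups). Every emitted molecule is valid,
uncharged, within the allowed element set, and passes the default
filters; the number of distinct Bemis–Murcko scaffolds is bounded by
`scaffold_pool`, so scaffold splits and substructure statistics behave
like they do on a real screening collection. What the generator does
*not* emulate: the property ranges of a lead-like collection (fixture
molecules are lighter than 250–350 Da leads), stereochemistry, charged
functional groups, and the long tail of rare fragments in real data.
Tests passing on fixtures therefore demonstrate the correctness of the
machinery, not model quality on real chemistry.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic
sets: 100–500-molecule corpora for the baselines, a 2,000-molecule set
for the split identities, 1,000 samples per generator seed and three
seeds for replicate summaries — sizes at which every metric is exercised
end-to-end in minutes on one core. All randomness flows through
per-call integer seeds with a pinned RNG kind, so results are
reproducible across sessions and calling contexts; `run_benchmark()` is
a pure function of its inputs, configuration and seeds.

## Known limitations

* The default Fréchet embedding is a descriptor stand-in; comparisons
  with activation-based FCD numbers require supplying activation
  matrices.
* Neural baselines are out of scope; their sample files are evaluated
  with `evaluate()` like any other generated set.
* SMILES is the only representation; InChI/SELFIES input and
  graph-native models are not supported.
* Whether duplicate generated draws should count once or per draw in
  novelty is a convention; per-draw is implemented and documented
  above.
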