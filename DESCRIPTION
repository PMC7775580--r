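Package: molbench
Title: Distribution-Learning Benchmarks for Molecular Generative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarking platform for molecular distribution-learning
    generative models working on SMILES strings. Provides the standard
    evaluation metrics (validity, uniqueness, novelty, filter compliance,
    BRICS-fragment and Bemis-Murcko-scaffold cosine similarity,
    nearest-neighbor Tanimoto similarity, internal diversity, Frechet
    distance over pluggable molecule embeddings, and property-distribution
    Wasserstein-1 distances), a dataset-construction pipeline with
    medicinal-chemistry and PAINS structural filters and a
    scaffold-held-out three-way split, and three non-neural baseline
    generators (token n-gram, Baum-Welch hidden Markov model, and a
    BRICS-fragment combinatorial assembler). Molecule-level chemistry is
    delegated to an RDKit helper process; a synthetic fixture generator
    makes the whole platform testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (override via option 'molbench.python').
Config/testthat/edition: 3
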