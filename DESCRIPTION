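Package: AssayMolGen
Title: Retrieval-Augmented Molecule Generation from Screening-Assay Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning public screening-assay records into context for
    text-based molecule generation. Assay records (descriptive text plus
    tabular molecule outcomes) are embedded and retrieved by cosine
    similarity for a free-text protein or phenotype query, filtered by a
    cascade of rules (query-target exclusion, minimum table size, optional
    sequence-identity cap, model-judged relevance and counterscreen
    detection), distilled into a class-balanced in-context-learning prompt,
    and passed to a pluggable text-generation backend that proposes candidate
    molecules as SMILES. A metric suite (validity, drug-likeness, synthetic
    accessibility, fingerprint diversity, docking-score improvement over a
    background distribution) evaluates the candidates per target and across
    targets. Deterministic mock backends and a synthetic assay-corpus
    generator make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
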