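---
title: "Generating candidate molecules from screening-assay context"
author: "AssayMolGen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating candidate molecules from screening-assay context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AssayMolGen)
```

## The problem

Public screening repositories hold millions of assay records: free-text
descriptions of a biological target and protocol, together with tables of
tested molecules and their activity outcomes. For a new target described
only in words — a protein, or even a phenotype — those records are a rich
but unstructured source of structure-activity examples. AssayMolGen
implements a retrieval-augmented generation workflow over such records:

1. **Retrieve** assay records whose text is similar to the query
   description (embedding + cosine top-k).
2. **Filter** the candidates: drop assays of the query protein itself,
   drop under-populated tables, optionally drop near-identical protein
   targets, and ask a text model which assays are truly relevant and which
   are counterscreens.
3. **Distill** each surviving assay into a prompt block: a concise summary
   plus a class-balanced excerpt of its outcome table.
4. **Generate** candidate molecules (SMILES) with a pluggable
   text-generation backend, in small independent batches.
5. **Evaluate** the candidates: validity, drug-likeness (QED), synthetic
   accessibility, fingerprint diversity, heavy-atom size, and — when a
   scorer is available — docking-style scores, the high-affinity fraction
   and the improvement over a background score distribution.

Every model-dependent step sits behind a provider interface with a
deterministic offline implementation, so the entire pipeline is testable
without network access or model weights.

## Retrieval model

Texts are embedded into a fixed d-dimensional space; an assay corpus
becomes a matrix of vectors, and retrieval is exact cosine top-k:

$$\mathcal{I}_k = \operatorname{arg\,top\text{-}k}
  \frac{p \cdot b_i}{\lVert p\rVert \, \lVert b_i\rVert},
  \qquad i = 1, \dots, N,$$

with \(p\) the query embedding and \(b_i\) the embedding of record \(i\).
Embeddings are stored unnormalized; normalization happens inside the
cosine. Ties are broken by ascending assay identifier, which makes
retrieval fully deterministic — the tie rule is a reproducibility choice
the method itself does not prescribe. No approximate-nearest-neighbour
structure is used: corpora at the intended scale are searched exactly.

The shipped offline embedding provider is a salted hashed bag-of-tokens:
each lower-cased token hashes (FNV-1a) to one coordinate and a sign. It
involves no model and no randomness, and it makes text similarity
proportional to token overlap, which is exactly the property the synthetic
corpus exploits (below). An HTTP provider for OpenAI-compatible embedding
endpoints is included as thin, untested plumbing; the optional
keyword-condensation step before embedding is bypassable and off by
default, since its benefit depends entirely on the text backend.

## The filter cascade and its parameters

Filters are applied in a fixed order, and each can only shrink the
candidate set:

| parameter | default | meaning |
|---|---|---|
| `k` | 50 | initial retrieval depth |
| `minMolNum` | 4 | smallest outcome table kept (inclusive) |
| `maxAssayNum` | 10 | cap on assays in the final context |
| `nMol` | 8 | per-activity-class sample size |
| `maxMolSize` | 45 | heavy-atom ceiling for context molecules |
| `seqIdentityThreshold` | 0.30 | strict identity cap (optional stage) |

`maxAssayNum = 10`, `nMol = 8` and `maxMolSize = 45` follow the reference
configuration of the workflow. `minMolNum` has no published value; 4 is
this package's committed default — small enough to keep confirmatory
screens, large enough to drop single-molecule literature extractions — and
it is escalated to `2 * nMol` for assays with no active rows, which can
only contribute the all-molecules fallback and must be large enough to be
informative. The boundary is inclusive: a table of exactly `minMolNum`
rows passes, since the rule removes assays with *fewer* molecules.

The sequence-identity stage is off by default (it needs a query sequence
and an identity provider). It is strict: identity exactly at the threshold
is retained, identity *exceeding* it is discarded and the next-ranked
candidate takes its place until `maxAssayNum` survivors are collected. A
mock provider with planted identities serves tests; a real provider backed
by global pairwise alignment (Biostrings) is included.

Relevance and counterscreen status are judged per assay in a single
structured provider call (halving backend traffic relative to two separate
judgments, which the method leaves unspecified). The response must contain
a machine-parsable verdict block; one re-ask is allowed, after which the
assay defaults to not-relevant with a warning. When several providers
judge the same assay, their relevance verdicts combine by a configurable
rule (`or` / `and` / `majority`, default single-provider); the published
workflow aggregates two models without printing the rule, so `or` — keep
anything either model trusts — is the package's committed default.
Counterscreen assays are *kept*, not dropped: their actives become
avoid-examples in the prompt, mirroring how counterscreen actives are
negative evidence rather than noise.

The relevance ratio `x = relevant / total` stratifies targets into groups
with the boundaries taken literally from the published inequality chain:
High `x >= 0.7`, Medium `0.4 < x < 0.7`, Low `0.1 < x <= 0.4`, None
`x <= 0.1`. Note the asymmetry (0.7 belongs to High, 0.1 to None); the
grouping is enumeration-tested at every count out of 10.

## Layered context construction

Each selected assay contributes one prompt block, in similarity order
(another reproducibility choice):

* **Summary** — produced by the text provider; counterscreen-tagged assays
  get a template sentence appended stating that their active molecules
  should be avoided, so the instruction survives any summarization.
* **Table** — a deterministic fixed-column rendering
  (`smiles | outcome | measurement`), actives first, then input order.
  Measurements (standard type, relation, value, units) print as-is; rows
  are never re-ordered or thresholded by potency, because the selection
  rule below is explicitly *random* sampling, not potency ranking.
* **Molecule selection** — after pruning molecules with more than
  `maxMolSize` heavy atoms (strictly greater; rows with unparsable SMILES
  are dropped with a warning and counted rather than aborting the run):
  * more than `nMol` actives: a uniform sample of `nMol`;
  * 1 to `nMol` actives: all of them;
  * plus, for class balance, a uniform sample of `nMol` from the pooled
    Unspecified/Inactive rows (all of them when fewer exist — an
    under-supply case the rule does not address, resolved here by taking
    everything);
  * no actives at all: every molecule, unless the table exceeds
    `2 * nMol`, in which case a uniform sample of `2 * nMol`.

  Sampling is uniform *without replacement* from a seeded generator — the
  simplest reproducible reading of "randomly sample" — and each assay's
  selection seed is derived from the run seed and the assay id, so one
  assay's table never perturbs another's sample.

Prompt assembly is a pure function of (query, blocks, template version,
mode). The template is a versioned text asset of this package: the
reference workflow's exact prompt wordings are not published, so the
shipped templates paraphrase the described content. A token budget
(estimated as bytes/4, overridable) truncates the lowest-ranked blocks
with a warning when the context would overflow a backend's window. With
zero blocks the prompt degrades to description-only generation — the
ablation arm of the evaluation design.

In anti-target mode the same machinery runs against a counterscreen target
(e.g. the hERG cardiac channel): the context describes the anti-target,
the molecules to be optimized are appended verbatim, and the instruction
asks for one edited molecule per input that reduces anti-target activity
while preserving the original activity. Outputs pair positionally with
inputs (invalid outputs fall back to the input, flagged) so before/after
score deltas are well defined.

## Generation

Molecules are requested in batches of 10 by default: large batches induce
mode collapse (near-duplicate series within one response), so small
independent batches with identical prompts and no chat memory are used
instead. The response parser strips code fences and list markers, then
takes per line the longest whitespace-delimited token that canonicalizes
as SMILES; lines with no parsable token are kept as invalid candidates so
the validity rate reflects everything the backend emitted. Deduplication
is by canonical SMILES (on by default and config-exposed; whether the
reference workflow deduplicates before evaluation is unstated) and a call
budget bounds degenerate providers, returning a partial result with a
warning.

## Evaluation metrics

* **Validity** — fraction of emitted candidates that parse.
* **QED** and **SA** — computed with RDKit, the standard implementation of
  both, through a bundled batched helper. The raw Ertl SA score (1 easy to
  10 hard) is normalized as `sa_norm = 1 - (raw - 1)/9`, so 0 is hardest
  to synthesize, matching the orientation used in the reference
  evaluation.
* **Diversity** — mean pairwise `1 - Tanimoto` on circular fingerprints.
  "Morgan fingerprint" fixes neither radius nor width; radius 2 with 2048
  bits is the community default and this package's choice (config-exposed;
  OpenBabel's ECFP4 implementation, folded from 4096 to 2048 bits by OR).
* **Size** — heavy-atom count, tracked because docking scores correlate
  with molecule size.
* **High affinity** — fraction of generated molecules scoring strictly
  better (lower) than the reference score; with several references, their
  best. Both the strictness and the best-reference rule are documented
  package choices on points the method leaves silent.
* **Improvement** — mean over generated molecules of
  `mean(background) - score` against a target-specific background
  distribution (e.g. approved drugs docked to the same target). The mean
  is the default location functional, the median available by
  configuration; improvement is invariant to shifting all scores by a
  constant, which is what makes it comparable across targets with
  different score distributions.
* **Aggregation** — two-level: per-target means (and medians) first, then
  the cross-target mean and median of each. Both the mean-of-means and
  mean-of-medians columns are reported because the single-statistic
  version is ambiguous; with equal molecule counts per target the
  mean-of-means equals the flat mean, which is property-tested.

Docking engines and anti-target regressors are deliberately out of scope:
`MoleculeScorer` is an interface, with two shipped deterministic mocks (a
seeded hash scorer and a planted-effect scorer whose scores improve with
similarity to target-specific planted actives).

## The synthetic corpus: what it emulates, and what it does not

`makeCorpus()` is a first-class, tested module, not a throwaway fixture.
It emulates the *structural* features of public assay records that the
pipeline's correctness depends on: descriptive text with retrievable
target signal (planted family signature tokens, separable by construction
under the hash embedder), typed outcome tables with the three activity
labels and micromolar measurement records, counterscreen flags, shared
target accessions within a family, and target sequences. The ground-truth
manifest predicts every filter decision by direct predicate evaluation,
which is exactly what the oracle tests check.

Corpus parameters are fixed at realistic desk-scale values: tables of
6-40 molecules, about 30% actives, about 15% counterscreens, three target
families. The molecule pool (~340 structures) is built by decorating
twelve common scaffolds with a fixed substituent list, plus a few
well-known drugs; construction guarantees chemical validity and gives
controllable scaffold overlap, which the planted-effect scorer exploits.

What the synthetic corpus does **not** emulate: real repository prose
style, inter-assay text redundancy, measurement-unit heterogeneity,
assay-size distributions with heavy tails, or any true
structure-activity relationship. Passing the offline suite therefore
demonstrates that the pipeline's mechanics (retrieval, filtering,
selection, prompt assembly, metric computation) are correct and
deterministic — not that any particular text backend will generate potent
molecules for a real target.

## Numerical and design choices

* All randomness flows through explicit integer seeds; sampling restores
  the caller's RNG state, and generator kinds are pinned, so results are
  stable across platforms and call orders.
* Deterministic hashing (FNV-1a, 32-bit, exact in doubles) drives the mock
  embedder, prompt digests and mock scorers; no cryptographic hash is
  needed, only stability.
* Degenerate inputs fail loudly and early: zero-norm embeddings, dimension
  mismatches, empty corpora, empty outcome tables reaching selection, and
  partial measurement records are typed errors, not silent `NA`s. Invalid
  SMILES in *input tables* and in *generated output* are tolerated by
  design (dropped with a warning, or kept with `valid = FALSE`), because
  both occur routinely in real data.
* Expensive per-molecule chemistry (canonicalization, atom counts,
  fingerprints, QED/SA) is memoised in a session cache keyed by the input
  string; fixtures draw from a bounded pool, so the property suites run at
  scale (thousands of random tables, hundreds of metric oracles) in
  seconds to a couple of minutes.
* Test and acceptance problem sizes are the package's own choices:
  retrieval oracles at N = 1000, d = 64 over 20 corpora; 50 corpora for
  the filter-cascade oracle; 5000 random tables for selection invariants;
  100 random fixtures per metric oracle; end-to-end runs at 100 molecules
  in batches of 10; 20 seeded replicates for the planted-effect contrast.

## Known limitations

* The hash embedder measures token overlap only; it cannot rank by
  semantic similarity, and real deployments should plug in a proper
  embedding endpoint.
* The prompt templates are this package's paraphrase; backends sensitive
  to prompt wording will behave differently from any published numbers.
* Sequence identity via global alignment is a stand-in for a dedicated
  homology search tool and is quadratic in sequence length.
* QED/SA run through a Python helper (RDKit); a pure-R implementation of
  both metrics is not provided.
* The pipeline is SMILES-level throughout: no 3D conformers, no docking,
  no pose analysis.
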