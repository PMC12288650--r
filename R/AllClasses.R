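## S4 classes for assay records, queries, retrieval and generation artifacts.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' TargetInfo: the protein target annotation of an assay
#'
#' @slot uniprotId optional UniProt accession (`NA` when unknown).
#' @slot name free-text target name.
#' @slot sequence optional amino-acid sequence (standard one-letter codes).
#' @exportClass TargetInfo
setClass("TargetInfo", representation(
  uniprotId = "character", name = "character", sequence = "character"),
  prototype(uniprotId = NA_character_, name = "", sequence = NA_character_))

setValidity("TargetInfo", function(object) {
  seq <- object@sequence
  if (!is.na(seq) && !grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seq))
    return("sequence contains non-standard amino-acid letters")
  TRUE
})

#' Construct a TargetInfo
#' @param name target name.
#' @param uniprotId optional accession.
#' @param sequence optional amino-acid sequence.
#' @return a [TargetInfo-class] object.
#' @export
targetInfo <- function(name = "", uniprotId = NA_character_,
                       sequence = NA_character_) {
  new("TargetInfo", uniprotId = as.character(uniprotId), name = name,
      sequence = as.character(sequence))
}

setClassUnion("TargetInfoOrNULL", c("TargetInfo", "NULL"))

.outcomeLevels <- c("Active", "Unspecified", "Inactive")

#' BioAssayRecord: one screening-assay record
#'
#' A single assay: identifier, descriptive text fields, optional target
#' annotation, and an ordered outcome table of tested molecules (SMILES,
#' activity label, optional measurement). The optional counterscreen
#' annotation is a ground-truth flag used by synthetic fixtures; the pipeline
#' itself infers counterscreen status from text via a text provider.
#'
#' @slot aid positive integer assay identifier, unique within a corpus.
#' @slot title,description,protocol text fields.
#' @slot target optional [TargetInfo-class].
#' @slot outcomes data.frame with columns `smiles`, `outcome` (one of
#'   `Active`, `Unspecified`, `Inactive`), `std_type`, `relation`, `value`,
#'   `units`; the last four are `NA` when no measurement was reported.
#' @slot counterscreenAnnotation logical; `NA` when unannotated.
#' @slot metadata list preserving unrecognized JSON keys.
#' @exportClass BioAssayRecord
setClass("BioAssayRecord", representation(
  aid = "integer", title = "character", description = "character",
  protocol = "character", target = "TargetInfoOrNULL", outcomes = "data.frame",
  counterscreenAnnotation = "logical", metadata = "list"),
  prototype(counterscreenAnnotation = NA, metadata = list()))

emptyOutcomeTable <- function() {
  data.frame(smiles = character(), outcome = character(),
             std_type = character(), relation = character(),
             value = numeric(), units = character())
}

validateOutcomeTable <- function(df) {
  need <- c("smiles", "outcome", "std_type", "relation", "value", "units")
  if (!all(need %in% names(df)))
    return(sprintf("outcome table lacks column(s): %s",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(!df$outcome %in% .outcomeLevels)
  if (length(bad))
    return(sprintf("row %d has outcome label '%s'", bad[1], df$outcome[bad[1]]))
  hasm <- !is.na(df$std_type) | !is.na(df$relation) | !is.na(df$value) |
    !is.na(df$units)
  part <- hasm & (is.na(df$std_type) | is.na(df$relation) | is.na(df$value) |
                    is.na(df$units))
  if (any(part))
    return(sprintf("row %d has a partial measurement record", which(part)[1]))
  if (any(hasm & !df$relation %in% c("<", "=", ">")))
    return("measurement relation must be one of <, =, >")
  if (any(hasm & df$value < 0))
    return("measurement value must be non-negative")
  TRUE
}

setValidity("BioAssayRecord", function(object) {
  if (length(object@aid) != 1L || is.na(object@aid) || object@aid < 1L)
    return("aid must be a single positive integer")
  validateOutcomeTable(object@outcomes)
})

#' AssayAssessment: one relevance/counterscreen verdict
#'
#' @slot aid assay identifier.
#' @slot relevant was the assay judged relevant to the query?
#' @slot counterscreen was it judged a counterscreen?
#' @slot summary assay summary text (empty until summarization runs).
#' @exportClass AssayAssessment
setClass("AssayAssessment", representation(
  aid = "integer", relevant = "logical", counterscreen = "logical",
  summary = "character"),
  prototype(summary = ""))

#' ProteinQuery: a free-text target description
#'
#' @slot description non-empty free text describing the target protein or
#'   phenotype.
#' @slot uniprotId,pdbId optional identifiers.
#' @slot sequence optional amino-acid sequence.
#' @slot desiredActivity `"inhibition"`, `"activation"` or `"unspecified"`.
#' @exportClass ProteinQuery
setClass("ProteinQuery", representation(
  description = "character", uniprotId = "character", pdbId = "character",
  sequence = "character", desiredActivity = "character"),
  prototype(uniprotId = NA_character_, pdbId = NA_character_,
            sequence = NA_character_, desiredActivity = "unspecified"))

setValidity("ProteinQuery", function(object) {
  if (!nzchar(object@description)) return("description must be non-empty")
  if (!object@desiredActivity %in% c("inhibition", "activation", "unspecified"))
    return("desiredActivity must be inhibition, activation or unspecified")
  if (!is.na(object@sequence) &&
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", object@sequence))
    return("sequence contains non-standard amino-acid letters")
  TRUE
})

#' Construct a ProteinQuery
#' @param description free-text description of the target (required).
#' @param uniprotId,pdbId optional identifiers.
#' @param sequence optional amino-acid sequence.
#' @param desiredActivity desired direction of activity.
#' @return a [ProteinQuery-class] object.
#' @export
proteinQuery <- function(description, uniprotId = NA_character_,
                         pdbId = NA_character_, sequence = NA_character_,
                         desiredActivity = c("unspecified", "inhibition",
                                             "activation")) {
  new("ProteinQuery", description = description,
      uniprotId = as.character(uniprotId), pdbId = as.character(pdbId),
      sequence = as.character(sequence),
      desiredActivity = match.arg(desiredActivity))
}

#' RetrievalConfig: tunable parameters of the retrieval/filter cascade
#'
#' Defaults follow the reference configuration: up to 10 assays in context,
#' 8 molecules per activity class, a 45-heavy-atom ceiling on context
#' molecules, and a strict 30% sequence-identity cap when the optional
#' identity filter is enabled.
#'
#' @slot k initial retrieval depth.
#' @slot minMolNum minimum outcome-table size for an assay to be kept (raised
#'   to `2 * nMol` for assays without actives).
#' @slot maxAssayNum cap on assays in the final context.
#' @slot maxMolSize heavy-atom ceiling for context molecules.
#' @slot nMol per-activity-class sample size.
#' @slot seqIdentityThreshold identity fraction above which (strictly) an
#'   assay target is considered the same protein family and discarded.
#' @slot useIdentityFilter is the sequence-identity stage enabled?
#' @slot seed integer seed driving all sampling.
#' @exportClass RetrievalConfig
setClass("RetrievalConfig", representation(
  k = "integer", minMolNum = "integer", maxAssayNum = "integer",
  maxMolSize = "integer", nMol = "integer", seqIdentityThreshold = "numeric",
  useIdentityFilter = "logical", seed = "integer"))

setValidity("RetrievalConfig", function(object) {
  counts <- c(object@k, object@minMolNum, object@maxAssayNum,
              object@maxMolSize, object@nMol)
  if (any(is.na(counts)) || any(counts < 1L)) return("all counts must be >= 1")
  if (object@seqIdentityThreshold < 0 || object@seqIdentityThreshold > 1)
    return("seqIdentityThreshold must be in [0, 1]")
  TRUE
})

#' Construct a RetrievalConfig
#' @param k initial retrieval depth.
#' @param minMolNum minimum outcome-table size.
#' @param maxAssayNum cap on selected assays.
#' @param maxMolSize heavy-atom ceiling for context molecules.
#' @param nMol per-class sample size.
#' @param seqIdentityThreshold strict sequence-identity cap.
#' @param useIdentityFilter enable the optional identity stage.
#' @param seed integer seed for sampling.
#' @return a [RetrievalConfig-class] object.
#' @export
retrievalConfig <- function(k = 50L, minMolNum = 4L, maxAssayNum = 10L,
                            maxMolSize = 45L, nMol = 8L,
                            seqIdentityThreshold = 0.30,
                            useIdentityFilter = FALSE, seed = 1L) {
  new("RetrievalConfig", k = as.integer(k), minMolNum = as.integer(minMolNum),
      maxAssayNum = as.integer(maxAssayNum), maxMolSize = as.integer(maxMolSize),
      nMol = as.integer(nMol), seqIdentityThreshold = seqIdentityThreshold,
      useIdentityFilter = useIdentityFilter, seed = as.integer(seed))
}

#' AssayIndex: an in-memory exact vector index over a corpus
#'
#' @slot aids assay identifiers, one per row of `vectors`.
#' @slot vectors numeric matrix of embeddings (rows = assays).
#' @slot dim embedding dimension.
#' @slot providerTag label of the embedding provider that built the index.
#' @exportClass AssayIndex
setClass("AssayIndex", representation(
  aids = "integer", vectors = "matrix", dim = "integer",
  providerTag = "character"))

setValidity("AssayIndex", function(object) {
  if (nrow(object@vectors) != length(object@aids))
    return("one embedding row per aid required")
  if (ncol(object@vectors) != object@dim)
    return("vector dimension disagrees with dim")
  if (anyDuplicated(object@aids)) return("aids must be distinct")
  if (!all(is.finite(object@vectors))) return("embeddings must be finite")
  TRUE
})

#' MoleculeSelection: the class-balanced molecules chosen from one assay
#'
#' @slot actives outcome-table rows labelled `Active` that were selected.
#' @slot others selected rows from the pooled `Unspecified`/`Inactive`
#'   classes.
#' @slot allMode `TRUE` when the no-actives fallback was used (all molecules,
#'   capped at twice the per-class sample size).
#' @exportClass MoleculeSelection
setClass("MoleculeSelection", representation(
  actives = "data.frame", others = "data.frame", allMode = "logical"))

#' GenerationContext: the assembled prompt context
#'
#' @slot queryText the query description.
#' @slot blocks ordered list (similarity rank) of per-assay blocks, each a
#'   list with elements `assessment` ([AssayAssessment-class]), `table`
#'   (rendered text table) and `selection` ([MoleculeSelection-class]).
#' @slot avoidMolecules SMILES of counterscreen actives, framed as
#'   avoid-examples.
#' @slot optimizationTargets molecules to be optimized (anti-target mode).
#' @slot mode `"generate"` or `"optimize_anti_target"`.
#' @slot prompt the final prompt text.
#' @slot templateVersion version tag of the prompt template.
#' @exportClass GenerationContext
setClass("GenerationContext", representation(
  queryText = "character", blocks = "list", avoidMolecules = "character",
  optimizationTargets = "character", mode = "character", prompt = "character",
  templateVersion = "character"))

#' CorpusSpec: parameters of the synthetic assay-corpus generator
#'
#' @slot nAssays number of assay records.
#' @slot nFamilies number of synthetic target families.
#' @slot activesFraction expected fraction of `Active` rows per table.
#' @slot tableSizeRange integer (min, max) outcome-table sizes.
#' @slot counterscreenFraction fraction of assays flagged as counterscreens.
#' @slot seed integer seed; the corpus is a pure function of these
#'   parameters.
#' @exportClass CorpusSpec
setClass("CorpusSpec", representation(
  nAssays = "integer", nFamilies = "integer", activesFraction = "numeric",
  tableSizeRange = "integer", counterscreenFraction = "numeric",
  seed = "integer"))

setValidity("CorpusSpec", function(object) {
  if (object@activesFraction < 0 || object@activesFraction > 1 ||
      object@counterscreenFraction < 0 || object@counterscreenFraction > 1)
    return("fractions must lie in [0, 1]")
  if (length(object@tableSizeRange) != 2L ||
      object@tableSizeRange[1] > object@tableSizeRange[2])
    return("tableSizeRange must be (min, max) with min <= max")
  if (object@nAssays < 1L || object@nFamilies < 1L)
    return("nAssays and nFamilies must be >= 1")
  TRUE
})

#' Construct a CorpusSpec
#' @param nAssays number of assays.
#' @param nFamilies number of target families.
#' @param activesFraction expected per-table fraction of actives.
#' @param tableSizeRange (min, max) table sizes.
#' @param counterscreenFraction fraction of counterscreen assays.
#' @param seed integer seed.
#' @return a [CorpusSpec-class] object.
#' @export
corpusSpec <- function(nAssays = 50L, nFamilies = 3L, activesFraction = 0.3,
                       tableSizeRange = c(6L, 40L),
                       counterscreenFraction = 0.15, seed = 1L) {
  new("CorpusSpec", nAssays = as.integer(nAssays),
      nFamilies = as.integer(nFamilies), activesFraction = activesFraction,
      tableSizeRange = as.integer(tableSizeRange),
      counterscreenFraction = counterscreenFraction, seed = as.integer(seed))
}

## ---- provider interfaces ---------------------------------------------------

#' Virtual provider classes
#'
#' Backends are pluggable: embedding, text generation, molecule scoring
#' (docking or anti-target prediction) and sequence identity each sit behind
#' a small S4 interface with deterministic offline implementations used in
#' tests, plus thin HTTP plumbing for live endpoints.
#'
#' @name providers
#' @aliases EmbeddingProvider-class TextProvider-class MoleculeScorer-class
#'   SequenceIdentityProvider-class
NULL

#' @exportClass EmbeddingProvider
setClass("EmbeddingProvider", representation("VIRTUAL", tag = "character"))

#' @exportClass TextProvider
setClass("TextProvider", representation("VIRTUAL"))

#' @exportClass MoleculeScorer
setClass("MoleculeScorer", representation("VIRTUAL", tag = "character"))

#' @exportClass SequenceIdentityProvider
setClass("SequenceIdentityProvider", representation("VIRTUAL"))
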