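## Generics: accessors and provider interfaces.

#' Assay identifier
#' @param x a [BioAssayRecord-class] or [AssayAssessment-class].
#' @return integer assay identifier.
#' @export
setGeneric("aid", function(x) standardGeneric("aid"))

#' Outcome table of an assay
#' @param x a [BioAssayRecord-class].
#' @return data.frame of molecule outcomes.
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' Target annotation of an assay
#' @param x a [BioAssayRecord-class].
#' @return a [TargetInfo-class] or `NULL`.
#' @export
setGeneric("assayTarget", function(x) standardGeneric("assayTarget"))

#' Embed texts into a fixed-dimension vector space
#' @param provider an [EmbeddingProvider-class].
#' @param texts character vector.
#' @return numeric matrix, one row per text.
#' @export
setGeneric("embedText", function(provider, texts) standardGeneric("embedText"))

#' Answer a structured text request
#'
#' `request` is a list with at least `class` (one of `"keywords"`,
#' `"summarize"`, `"assess"`, `"generate"`, `"optimize"`) and `prompt`;
#' request classes may carry extra fields (`record`, `query`, `n`,
#' `molecules`).
#'
#' @param provider a [TextProvider-class].
#' @param request request list.
#' @return character scalar, the provider's raw text response.
#' @export
setGeneric("respondText",
           function(provider, request) standardGeneric("respondText"))

#' Score molecules against a target
#' @param scorer a [MoleculeScorer-class].
#' @param smiles character vector of SMILES.
#' @param targetId target identifier (scorers may condition on it).
#' @return numeric vector of scores (docking convention: lower is better).
#' @export
setGeneric("scoreMolecules", function(scorer, smiles, targetId)
  standardGeneric("scoreMolecules"))

#' Pairwise sequence identity
#' @param provider a [SequenceIdentityProvider-class].
#' @param seqA,seqB amino-acid sequences.
#' @return identity fraction in \[0, 1\].
#' @export
setGeneric("sequenceIdentity", function(provider, seqA, seqB)
  standardGeneric("sequenceIdentity"))

## accessors ------------------------------------------------------------------

#' @describeIn aid identifier of a record
#' @export
setMethod("aid", "BioAssayRecord", function(x) x@aid)

#' @describeIn aid identifier the assessment refers to
#' @export
setMethod("aid", "AssayAssessment", function(x) x@aid)

#' @describeIn outcomes outcome table of a record
#' @export
setMethod("outcomes", "BioAssayRecord", function(x) x@outcomes)

#' @describeIn assayTarget target of a record
#' @export
setMethod("assayTarget", "BioAssayRecord", function(x) x@target)

setMethod("show", "BioAssayRecord", function(object) {
  tab <- table(factor(object@outcomes$outcome, levels = .outcomeLevels))
  cat(sprintf("BioAssayRecord AID %d: %s\n", object@aid, object@title))
  cat(sprintf("  outcomes: %d (%s)\n", nrow(object@outcomes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  if (!is.null(object@target))
    cat(sprintf("  target: %s [%s]\n", object@target@name,
                object@target@uniprotId))
  if (isTRUE(object@counterscreenAnnotation))
    cat("  annotated counterscreen\n")
})

setMethod("show", "ProteinQuery", function(object) {
  cat(sprintf("ProteinQuery (%s): %s\n", object@desiredActivity,
              substr(object@description, 1, 70)))
})

setMethod("show", "AssayIndex", function(object) {
  cat(sprintf("AssayIndex: %d assays, d = %d, provider '%s'\n",
              length(object@aids), object@dim, object@providerTag))
})

setMethod("show", "GenerationContext", function(object) {
  cat(sprintf("GenerationContext (%s): %d block(s), %d avoid molecule(s), ~%d tokens\n",
              object@mode, length(object@blocks),
              length(object@avoidMolecules), estimateTokens(object@prompt)))
})

setMethod("show", "CorpusSpec", function(object) {
  cat(sprintf("CorpusSpec: %d assays, %d families, seed %d\n",
              object@nAssays, object@nFamilies, object@seed))
})
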