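## End-to-end orchestration: corpus -> index -> retrieve -> context ->
## generate -> evaluate.

#' Run the full generation pipeline
#'
#' Convenience orchestrator wiring the stages together: embed and retrieve
#' assays for the query, filter and assess them, build the layered context
#' prompt, generate molecules in batches, and (optionally) evaluate them
#' with a scorer against a background distribution. All stages are pure
#' functions of their inputs and the config seed, so a fixed configuration
#' reproduces byte-identical results.
#'
#' @param query a [ProteinQuery-class].
#' @param corpus named list of [BioAssayRecord-class] objects.
#' @param config a [RetrievalConfig-class].
#' @param embeddingProvider an [EmbeddingProvider-class].
#' @param assessProvider a [TextProvider-class] for relevance/counterscreen
#'   assessment and summaries.
#' @param generationProvider a [TextProvider-class] for molecule generation.
#' @param nTotal number of molecules to generate.
#' @param batchSize molecules per generation call.
#' @param index optional pre-built [AssayIndex-class] (rebuilt when `NULL`).
#' @param scorer optional [MoleculeScorer-class].
#' @param targetId target id passed to the scorer (default: query
#'   description).
#' @param baselineScores optional background scores for improvement.
#' @param refScore optional reference score for the high-affinity fraction.
#' @param identityProvider optional [SequenceIdentityProvider-class].
#' @return list with `retrieval` (from [retrieveAssays()]), `context`
#'   ([GenerationContext-class]), `molecules` (from [generateN()]),
#'   `validity` (validity rate) and `report` (from [evaluateTarget()], or
#'   `NULL` without a scorer).
#' @export
runGenerationPipeline <- function(query, corpus, config,
                                  embeddingProvider, assessProvider,
                                  generationProvider, nTotal = 100L,
                                  batchSize = 10L, index = NULL,
                                  scorer = NULL, targetId = NULL,
                                  baselineScores = NULL, refScore = NULL,
                                  identityProvider = NULL) {
  if (is.null(index)) index <- buildAssayIndex(corpus, embeddingProvider)
  retrieval <- retrieveAssays(query, index, corpus, config,
                              embeddingProvider, assessProvider,
                              identityProvider)
  blocks <- buildContextBlocks(retrieval$selected, corpus, query, config,
                               assessProvider)
  context <- buildPrompt(query, blocks, mode = "generate",
                         batchSize = batchSize)
  molecules <- generateN(context, generationProvider, nTotal, batchSize)
  validMols <- unique(molecules$smiles[molecules$valid])
  report <- NULL
  if (!is.null(scorer) && length(validMols)) {
    if (is.null(targetId)) targetId <- query@description
    report <- evaluateTarget(
      targetId, validMols, scorer = scorer, refScore = refScore,
      baselineScores = baselineScores,
      relevanceGroup = if (!is.null(retrieval$ratio))
        as.character(retrieval$ratio$group) else NA)
  }
  list(retrieval = retrieval, context = context, molecules = molecules,
       validity = validityRate(molecules), report = report)
}
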