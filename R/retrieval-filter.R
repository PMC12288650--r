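## The retrieval filter cascade: query-target exclusion, minimum table size
## (with the no-actives escalation), optional sequence-identity cap,
## model-judged relevance / counterscreen assessment, and final selection.

corpusRecord <- function(corpus, aidValue) {
  rec <- corpus[[as.character(aidValue)]]
  if (is.null(rec))
    amgStop("amg_contract_error", "aid %s not present in corpus", aidValue)
  rec
}

#' Exclude assays that directly involve the query protein
#'
#' Assays whose target UniProt accession equals the query's accession are
#' removed so generation cannot trivially copy the query protein's own
#' screening data. A no-op when the query carries no accession.
#'
#' @param results retrieval data.frame (`aid`, `similarity`).
#' @param corpus named list of [BioAssayRecord-class] objects.
#' @param query a [ProteinQuery-class].
#' @return filtered retrieval data.frame, order preserved.
#' @export
excludeQueryTarget <- function(results, corpus, query) {
  if (is.na(query@uniprotId)) return(results)
  keep <- vapply(results$aid, function(a) {
    tgt <- assayTarget(corpusRecord(corpus, a))
    is.null(tgt) || is.na(tgt@uniprotId) || tgt@uniprotId != query@uniprotId
  }, logical(1))
  results[keep, , drop = FALSE]
}

nActiveRows <- function(record) sum(outcomes(record)$outcome == "Active")

#' Drop assays with too few tested molecules
#'
#' Removes assays whose outcome table is shorter than `minMolNum` (boundary
#' inclusive: a table of exactly `minMolNum` rows is kept). For assays with
#' no active molecules the threshold is raised to `2 * nMol`, since such
#' assays can only contribute the all-molecules fallback selection and need
#' enough rows to be informative.
#'
#' @param results retrieval data.frame.
#' @param corpus named record list.
#' @param minMolNum minimum table size.
#' @param nMol per-class sample size (drives the no-actives escalation).
#' @return filtered retrieval data.frame.
#' @export
filterMinMolecules <- function(results, corpus, minMolNum, nMol) {
  keep <- vapply(results$aid, function(a) {
    rec <- corpusRecord(corpus, a)
    threshold <- if (nActiveRows(rec) == 0L) max(minMolNum, 2L * nMol)
                 else minMolNum
    nrow(outcomes(rec)) >= threshold
  }, logical(1))
  results[keep, , drop = FALSE]
}

#' Drop assays whose target is too similar to the query protein
#'
#' Walks the ranked candidates in order; an assay whose target sequence
#' identity to the query exceeds `threshold` (strictly: exactly the
#' threshold is retained) is discarded and replaced by the next candidate,
#' until `maxAssayNum` survivors are collected or candidates are exhausted.
#' Assays without a target sequence pass with a warning. This optional stage
#' guards against leakage from near-identical proteins.
#'
#' @param results retrieval data.frame.
#' @param corpus named record list.
#' @param query a [ProteinQuery-class] with a sequence.
#' @param threshold identity fraction in \[0, 1\].
#' @param identityProvider a [SequenceIdentityProvider-class].
#' @param maxAssayNum stop after this many survivors (default: keep all).
#' @return filtered retrieval data.frame.
#' @export
filterSequenceIdentity <- function(results, corpus, query, threshold,
                                   identityProvider, maxAssayNum = Inf) {
  if (is.na(query@sequence))
    amgStop("amg_contract_error",
            "identity filter requires a query sequence")
  keep <- logical(nrow(results))
  collected <- 0L
  for (i in seq_len(nrow(results))) {
    if (collected >= maxAssayNum) break
    tgt <- assayTarget(corpusRecord(corpus, results$aid[i]))
    if (is.null(tgt) || is.na(tgt@sequence)) {
      amgWarn("assay %d has no target sequence; passing identity filter",
              results$aid[i])
      keep[i] <- TRUE
    } else {
      ident <- sequenceIdentity(identityProvider, query@sequence,
                                tgt@sequence)
      keep[i] <- ident <= threshold
    }
    if (keep[i]) collected <- collected + 1L
  }
  results[keep, , drop = FALSE]
}

parseVerdict <- function(text) {
  rel <- regmatches(text, regexpr("RELEVANT:\\s*(yes|no)", text,
                                  ignore.case = TRUE))
  cs <- regmatches(text, regexpr("COUNTERSCREEN:\\s*(yes|no)", text,
                                 ignore.case = TRUE))
  if (!length(rel) || !length(cs)) return(NULL)
  list(relevant = grepl("yes", rel, ignore.case = TRUE),
       counterscreen = grepl("yes", cs, ignore.case = TRUE))
}

assessmentPrompt <- function(record, query) {
  paste0(
    "You are reviewing a screening-assay record for a molecule-design query.\n",
    "Query target: ", query@description, "\n",
    "Assay title: ", record@title, "\n",
    "Assay description: ", record@description, "\n",
    "Assay protocol: ", record@protocol, "\n",
    "Answer with exactly two lines:\n",
    "RELEVANT: yes|no (is this assay informative for the query target?)\n",
    "COUNTERSCREEN: yes|no (does it test an off-target/anti-target or ",
    "detect false positives, so its actives should be avoided?)")
}

#' Assess one assay's relevance and counterscreen status
#'
#' Asks the text provider for a machine-parsable verdict block (one call
#' covering both judgments). An unparsable response triggers exactly one
#' re-ask; if that also fails, the assay defaults to not-relevant /
#' not-counterscreen with a warning.
#'
#' @param record a [BioAssayRecord-class].
#' @param query a [ProteinQuery-class].
#' @param textProvider a [TextProvider-class].
#' @return an [AssayAssessment-class].
#' @export
assessAssay <- function(record, query, textProvider) {
  req <- list(class = "assess", prompt = assessmentPrompt(record, query),
              record = record, query = query)
  verdict <- parseVerdict(respondText(textProvider, req))
  if (is.null(verdict)) verdict <- parseVerdict(respondText(textProvider, req))
  if (is.null(verdict)) {
    amgWarn("unparsable assessment for assay %d twice; defaulting to not relevant",
            aid(record))
    verdict <- list(relevant = FALSE, counterscreen = FALSE)
  }
  new("AssayAssessment", aid = aid(record), relevant = verdict$relevant,
      counterscreen = verdict$counterscreen)
}

#' Aggregate assessments from several providers
#'
#' When more than one text provider judges relevance, the verdicts are
#' combined per assay by the chosen rule (`"or"`, `"and"`, or `"majority"`);
#' counterscreen flags combine by `"or"` (any provider flagging a
#' counterscreen marks it). With a single provider this reduces to
#' [assessAssay()].
#'
#' @param record a [BioAssayRecord-class].
#' @param query a [ProteinQuery-class].
#' @param textProviders list of [TextProvider-class] objects.
#' @param rule aggregation rule for the relevance verdict.
#' @return an [AssayAssessment-class].
#' @export
assessAssayAggregate <- function(record, query, textProviders,
                                 rule = c("or", "and", "majority")) {
  rule <- match.arg(rule)
  parts <- lapply(textProviders, function(p) assessAssay(record, query, p))
  rel <- vapply(parts, function(a) a@relevant, logical(1))
  relevant <- switch(rule, or = any(rel), and = all(rel),
                     majority = mean(rel) > 0.5)
  new("AssayAssessment", aid = aid(record), relevant = relevant,
      counterscreen = any(vapply(parts, function(a) a@counterscreen,
                                 logical(1))))
}

#' Select the final assay set
#'
#' Keeps assays judged relevant, in similarity order, truncated at
#' `maxAssayNum`. Counterscreen assays are retained (not dropped) and stay
#' tagged: downstream, their active molecules become avoid-examples rather
#' than templates.
#'
#' @param results retrieval data.frame (similarity order).
#' @param assessments list of [AssayAssessment-class], any order.
#' @param maxAssayNum cap on the selected set.
#' @return data.frame `aid`, `similarity`, `counterscreen` (possibly empty:
#'   with no relevant assays the pipeline falls back to description-only
#'   generation).
#' @export
selectAssays <- function(results, assessments, maxAssayNum) {
  byAid <- setNames(assessments, vapply(assessments, aid, integer(1)))
  keep <- vapply(results$aid, function(a) {
    a <- byAid[[as.character(a)]]
    !is.null(a) && a@relevant
  }, logical(1))
  out <- results[keep, , drop = FALSE]
  out <- head(out, maxAssayNum)
  out$counterscreen <- vapply(out$aid, function(a)
    byAid[[as.character(a)]]@counterscreen, logical(1))
  rownames(out) <- NULL
  out
}

#' Relevance ratio and relevance group
#'
#' `x` is the fraction of retrieved assays judged relevant. Targets are
#' stratified into groups by the inequalities: High `x >= 0.7`; Medium
#' `0.4 < x < 0.7`; Low `0.1 < x <= 0.4`; None `x <= 0.1`.
#'
#' @param assessments non-empty list of [AssayAssessment-class].
#' @return list with elements `x` (fraction) and `group` (factor level).
#' @export
relevanceRatio <- function(assessments) {
  if (!length(assessments))
    amgStop("amg_contract_error", "no assessments to summarize")
  x <- mean(vapply(assessments, function(a) a@relevant, logical(1)))
  group <- if (x >= 0.7) "High" else if (x > 0.4) "Medium"
           else if (x > 0.1) "Low" else "None"
  list(x = x, group = factor(group, levels = c("High", "Medium", "Low",
                                               "None")))
}

#' Run the full retrieval-and-filter cascade
#'
#' Embeds the query, retrieves the top `k` assays, then applies the filter
#' cascade in order: query-target exclusion, minimum-table-size filter (with
#' the no-actives escalation), optional sequence-identity filter, per-assay
#' relevance/counterscreen assessment, and selection truncated to
#' `maxAssayNum`. Each stage can only shrink the candidate set. An audit log
#' records every stage's surviving aids.
#'
#' @param query a [ProteinQuery-class].
#' @param index an [AssayIndex-class] built over `corpus`.
#' @param corpus named record list.
#' @param config a [RetrievalConfig-class].
#' @param embeddingProvider provider used for the query embedding (must
#'   match the index).
#' @param textProvider a [TextProvider-class] (or list of them, aggregated
#'   with the `"or"` rule) for assessment.
#' @param identityProvider optional [SequenceIdentityProvider-class];
#'   required when `config@useIdentityFilter` is `TRUE`.
#' @return list with `selected` (data.frame `aid`, `similarity`,
#'   `counterscreen`), `assessments` (all assessed assays), `ratio` (from
#'   [relevanceRatio()], `NULL` when nothing was assessed) and `audit`
#'   (named list of aid vectors per stage).
#' @export
retrieveAssays <- function(query, index, corpus, config,
                           embeddingProvider, textProvider,
                           identityProvider = NULL) {
  qvec <- embedQuery(query, embeddingProvider)
  results <- topK(index, qvec, config@k)
  audit <- list(retrieved = results$aid)
  results <- excludeQueryTarget(results, corpus, query)
  audit$after_uniprot_exclusion <- results$aid
  results <- filterMinMolecules(results, corpus, config@minMolNum, config@nMol)
  audit$after_min_molecules <- results$aid
  if (config@useIdentityFilter) {
    if (is.null(identityProvider))
      amgStop("amg_contract_error",
              "identity filter enabled but no identity provider given")
    results <- filterSequenceIdentity(results, corpus, query,
                                      config@seqIdentityThreshold,
                                      identityProvider, config@maxAssayNum)
    audit$after_identity <- results$aid
  }
  providers <- if (is(textProvider, "TextProvider")) list(textProvider)
               else textProvider
  assessments <- lapply(results$aid, function(a)
    assessAssayAggregate(corpusRecord(corpus, a), query, providers, "or"))
  selected <- selectAssays(results, assessments, config@maxAssayNum)
  audit$selected <- selected$aid
  ratio <- if (length(assessments)) relevanceRatio(assessments) else NULL
  list(selected = selected, assessments = assessments, ratio = ratio,
       audit = audit)
}
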