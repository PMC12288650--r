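## Layered contextual analysis: size pruning, class-balanced molecule
## selection, deterministic table rendering, per-assay summaries, and final
## prompt assembly.

promptTemplateVersion <- "1.0"

#' Prune oversized molecules from an outcome table
#'
#' Rows whose molecule has strictly more than `maxMolSize` heavy atoms are
#' removed; a molecule of exactly `maxMolSize` atoms is retained. Keeping
#' context molecules small counters the tendency of docking scores (and
#' generated molecules) to grow with atom count. Rows with unparsable SMILES
#' are dropped with a warning rather than aborting the run.
#'
#' @param outcomes outcome data.frame.
#' @param maxMolSize heavy-atom ceiling.
#' @return pruned outcome data.frame; the number of dropped invalid rows is
#'   attached as attribute `invalidDropped`.
#' @export
pruneBySize <- function(outcomes, maxMolSize) {
  stopifnot(maxMolSize >= 1)
  if (!nrow(outcomes)) return(outcomes)
  valid <- isValidSmiles(outcomes$smiles)
  if (any(!valid))
    amgWarn("dropping %d outcome row(s) with invalid SMILES", sum(!valid))
  outcomes <- outcomes[valid, , drop = FALSE]
  keep <- if (nrow(outcomes)) heavyAtomCount(outcomes$smiles) <= maxMolSize
          else logical(0)
  out <- outcomes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "invalidDropped") <- sum(!valid)
  out
}

#' Class-balanced molecule selection from an outcome table
#'
#' Implements the selection rules used to build the in-context examples,
#' with `nMol` the per-class sample size:
#' * more than `nMol` actives: a uniform sample of `nMol` actives;
#' * 1 to `nMol` actives: all of them;
#' * in both cases, a uniform sample of `nMol` molecules from the pooled
#'   `Unspecified`/`Inactive` classes (all of them if fewer exist), for
#'   class balance;
#' * no actives: fall back to all molecules, or a uniform sample of
#'   `2 * nMol` when the table exceeds that.
#'
#' Sampling is uniform without replacement and a pure function of `seed`.
#'
#' @param outcomes outcome data.frame, already pruned by size.
#' @param nMol per-class sample size.
#' @param seed integer seed.
#' @return a [MoleculeSelection-class].
#' @export
selectMolecules <- function(outcomes, nMol, seed) {
  stopifnot(nMol >= 1)
  if (!nrow(outcomes))
    amgStop("amg_contract_error",
            "empty outcome table (should have been filtered upstream)")
  isActive <- outcomes$outcome == "Active"
  act <- outcomes[isActive, , drop = FALSE]
  oth <- outcomes[!isActive, , drop = FALSE]
  withLocalSeed(seed, {
    if (nrow(act) == 0L) {
      sel <- if (nrow(oth) > 2L * nMol)
        oth[sort(sample.int(nrow(oth), 2L * nMol)), , drop = FALSE]
      else oth
      rownames(sel) <- NULL
      new("MoleculeSelection", actives = act[0, , drop = FALSE],
          others = sel, allMode = TRUE)
    } else {
      if (nrow(act) > nMol)
        act <- act[sort(sample.int(nrow(act), nMol)), , drop = FALSE]
      if (nrow(oth) > nMol)
        oth <- oth[sort(sample.int(nrow(oth), nMol)), , drop = FALSE]
      rownames(act) <- rownames(oth) <- NULL
      new("MoleculeSelection", actives = act, others = oth, allMode = FALSE)
    }
  })
}

formatMeasurement <- function(df) {
  ifelse(is.na(df$std_type), "",
         sprintf("%s %s %s %s", df$std_type, df$relation,
                 vapply(df$value, function(v) sprintf("%.6g", v), character(1)),
                 df$units))
}

#' Render an outcome table as fixed-column text
#'
#' Deterministic, byte-stable rendering used inside prompts: a header line,
#' then one row per molecule with columns `smiles | outcome | measurement`.
#' Actives come first, then the remaining rows in input order; the
#' measurement column is empty when no measurement was reported.
#'
#' @param x a [MoleculeSelection-class] or an outcome data.frame.
#' @return character scalar of rendered text.
#' @export
renderOutcomeTable <- function(x) {
  df <- if (is(x, "MoleculeSelection")) rbind(x@actives, x@others)
        else rbind(x[x$outcome == "Active", , drop = FALSE],
                   x[x$outcome != "Active", , drop = FALSE])
  header <- "smiles | outcome | measurement"
  if (!nrow(df)) return(header)
  rows <- sprintf("%s | %s | %s", df$smiles, df$outcome, formatMeasurement(df))
  paste(c(header, trimws(rows, which = "right")), collapse = "\n")
}

counterscreenClause <- paste(
  "This assay is a counterscreen:",
  "its active molecules should be avoided.")

#' Summarize an assay through a text provider
#'
#' Requests a concise summary capturing the assay's purpose, methodology and
#' key results and its apparent relationship to the query target. For
#' counterscreen-tagged assays an explicit avoidance sentence is appended by
#' template, so the generation prompt always states that counterscreen
#' actives are to be avoided.
#'
#' @param record a [BioAssayRecord-class].
#' @param query a [ProteinQuery-class].
#' @param textProvider a [TextProvider-class].
#' @param counterscreen is the assay counterscreen-tagged?
#' @return non-empty summary text.
#' @export
summarizeAssay <- function(record, query, textProvider,
                           counterscreen = FALSE) {
  prompt <- paste0(
    "Summarize this screening assay concisely: its purpose, methodology and ",
    "key results, and how its findings relate to the query target '",
    query@description, "'.\nTitle: ", record@title,
    "\nDescription: ", record@description, "\nProtocol: ", record@protocol)
  text <- respondText(textProvider, list(class = "summarize", prompt = prompt,
                                         record = record, query = query))
  if (!nzchar(text))
    amgStop("amg_backend_error", "empty summary for assay %d", aid(record))
  if (counterscreen) text <- paste(text, counterscreenClause)
  text
}

#' Assemble the per-assay context blocks
#'
#' For each selected assay (in similarity order): summarize it, prune its
#' outcome table by molecule size, select a class-balanced molecule set, and
#' render the table. Counterscreen actives are additionally collected as
#' avoid-examples.
#'
#' @param selected data.frame from [selectAssays()] (`aid`, `similarity`,
#'   `counterscreen`).
#' @param corpus named record list.
#' @param query a [ProteinQuery-class].
#' @param config a [RetrievalConfig-class].
#' @param textProvider a [TextProvider-class] for summaries.
#' @return list of blocks, each `list(assessment, table, selection)`, plus
#'   attribute `avoidMolecules`.
#' @export
buildContextBlocks <- function(selected, corpus, query, config, textProvider) {
  avoid <- character()
  blocks <- vector("list", nrow(selected))
  for (i in seq_len(nrow(selected))) {
    rec <- corpusRecord(corpus, selected$aid[i])
    cs <- selected$counterscreen[i]
    summary <- summarizeAssay(rec, query, textProvider, counterscreen = cs)
    pruned <- pruneBySize(outcomes(rec), config@maxMolSize)
    selection <- selectMolecules(pruned, config@nMol,
                                 deriveSeed(config@seed, selected$aid[i]))
    if (cs) avoid <- c(avoid, selection@actives$smiles)
    blocks[[i]] <- list(
      assessment = new("AssayAssessment", aid = aid(rec), relevant = TRUE,
                       counterscreen = cs, summary = summary),
      table = renderOutcomeTable(selection),
      selection = selection)
  }
  attr(blocks, "avoidMolecules") <- unique(avoid)
  blocks
}

#' Build the final generation prompt
#'
#' Assembles a deterministic prompt from a versioned template: the query
#' description, then each assay block (summary plus rendered table) in
#' similarity order, then the instruction block. With zero blocks the prompt
#' degrades to description-only generation. In `optimize_anti_target` mode
#' the molecules to be optimized are appended verbatim together with the
#' anti-target framing (reduce activity against the assayed target while
#' preserving the molecules' original activity).
#'
#' If the estimated prompt size exceeds `tokenBudget` (a chars/4 heuristic),
#' the lowest-ranked blocks are dropped with a warning until it fits.
#'
#' @param query a [ProteinQuery-class].
#' @param blocks block list from [buildContextBlocks()] (may be empty).
#' @param mode `"generate"` or `"optimize_anti_target"`.
#' @param optimizationTargets SMILES to optimize (required in optimize mode).
#' @param batchSize number of molecules requested per generation call.
#' @param tokenBudget prompt budget in estimated tokens.
#' @return a [GenerationContext-class] (its `prompt` slot holds the text).
#' @export
buildPrompt <- function(query, blocks, mode = c("generate",
                                                "optimize_anti_target"),
                        optimizationTargets = character(), batchSize = 10L,
                        tokenBudget = 24000L) {
  mode <- match.arg(mode)
  if (mode == "optimize_anti_target" && !length(optimizationTargets))
    amgStop("amg_contract_error",
            "optimize mode requires optimization targets")
  avoid <- attr(blocks, "avoidMolecules") %||% character()
  assemble <- function(blks) {
    parts <- c(sprintf("Query target (%s): %s", query@desiredActivity,
                       query@description))
    for (i in seq_along(blks)) {
      b <- blks[[i]]
      parts <- c(parts,
                 sprintf("--- Assay %d (AID %d)%s ---", i, b$assessment@aid,
                         if (b$assessment@counterscreen) " [counterscreen]"
                         else ""),
                 b$assessment@summary, b$table)
    }
    instruction <- if (mode == "generate") {
      sprintf(paste0(
        "Using the assay context above, propose %d new candidate molecules ",
        "with the desired activity for the query target. Output exactly %d ",
        "SMILES strings, one per line, and nothing else."),
        batchSize, batchSize)
    } else {
      paste0("The assay context above describes an anti-target. Optimize each ",
             "of the following molecules to reduce its activity against this ",
             "anti-target while preserving its original activity. Output one ",
             "optimized SMILES per input molecule, one per line, in the same ",
             "order:\n", paste(optimizationTargets, collapse = "\n"))
    }
    if (length(avoid))
      instruction <- paste0(
        "Avoid molecules similar to these counterscreen actives:\n",
        paste(avoid, collapse = "\n"), "\n", instruction)
    paste(c(parts, instruction), collapse = "\n\n")
  }
  prompt <- assemble(blocks)
  nDropped <- 0L
  while (estimateTokens(prompt) > tokenBudget && length(blocks)) {
    blocks <- blocks[-length(blocks)]
    nDropped <- nDropped + 1L
    prompt <- assemble(blocks)
  }
  if (nDropped > 0L)
    amgWarn("prompt over token budget; dropped %d lowest-ranked block(s)",
            nDropped)
  new("GenerationContext", queryText = query@description, blocks = blocks,
      avoidMolecules = avoid, optimizationTargets = optimizationTargets,
      mode = mode, prompt = prompt, templateVersion = promptTemplateVersion)
}
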