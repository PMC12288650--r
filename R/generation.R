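## Batched molecule generation: provider calls, SMILES extraction from raw
## responses, validation, deduplication, and the anti-target optimization
## loop.

#' Extract SMILES candidates from a raw text response
#'
#' Extraction rule (documented and oracle-tested): strip markup fences
#' (```` ``` ```` lines) and list markers, split into non-empty lines, and
#' for each line take the longest whitespace-delimited token that
#' canonicalizes as SMILES; if no token on a line parses, the longest token
#' is kept as an invalid candidate. Providers wrapping SMILES in prose or
#' code fences therefore yield the same molecules as bare-line output.
#'
#' @param text raw provider response.
#' @return data.frame with columns `smiles` (canonical, or the raw token
#'   when invalid), `raw_text` (the source line) and `valid`.
#' @export
extractSmilesCandidates <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[!grepl("^\\s*```", lines)]
  lines <- sub("^\\s*(\\d+[.)]|[-*+])\\s+", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  res <- lapply(lines, function(line) {
    toks <- strsplit(line, "\\s+")[[1]]
    toks <- toks[order(-nchar(toks))]
    can <- canonicalizeSmiles(toks, onInvalid = "na")
    hit <- which(!is.na(can))
    if (length(hit))
      list(smiles = can[hit[1]], raw = line, valid = TRUE)
    else
      list(smiles = toks[1], raw = line, valid = FALSE)
  })
  data.frame(
    smiles = vapply(res, `[[`, character(1), "smiles"),
    raw_text = vapply(res, `[[`, character(1), "raw"),
    valid = vapply(res, `[[`, logical(1), "valid"))
}

#' Generate one batch of candidate molecules
#'
#' Asks the text provider for exactly `batchSize` molecules given the
#' context prompt and parses the response with [extractSmilesCandidates()].
#' Invalid candidates are kept with `valid = FALSE` so validity rates can be
#' computed downstream.
#'
#' @param context a [GenerationContext-class].
#' @param provider a [TextProvider-class].
#' @param batchSize molecules requested per call (default 10).
#' @param batchIndex index recorded on the emitted molecules.
#' @return data.frame of generated molecules: `smiles`, `raw_text`,
#'   `batch_index`, `valid`, `context_hash`.
#' @export
generateBatch <- function(context, provider, batchSize = 10L,
                          batchIndex = 0L) {
  stopifnot(batchSize >= 1)
  response <- withRetries(function()
    respondText(provider, list(class = "generate", prompt = context@prompt,
                               n = batchSize, context = context)))
  cand <- extractSmilesCandidates(response)
  if (!nrow(cand)) {
    amgWarn("batch %d produced no parsable candidates", batchIndex)
    cand <- data.frame(smiles = character(), raw_text = character(),
                       valid = logical())
  }
  cand$batch_index <- rep(as.integer(batchIndex), nrow(cand))
  cand$context_hash <- rep(fnvDigest(context@prompt), nrow(cand))
  cand[c("smiles", "raw_text", "batch_index", "valid", "context_hash")]
}

#' Generate molecules until a target count is reached
#'
#' Issues repeated independent batch calls (identical prompts, no chat
#' memory: fresh batches counter mode collapse) until `nTotal` valid --
#' unique, when `dedupe` -- molecules are collected or `maxCalls` is
#' exhausted, in which case a partial result is returned with a warning.
#' Deduplication is by canonical SMILES, so two spellings of one molecule
#' never both survive.
#'
#' @param context a [GenerationContext-class].
#' @param provider a [TextProvider-class].
#' @param nTotal number of valid molecules wanted.
#' @param batchSize molecules per provider call.
#' @param dedupe drop duplicate molecules?
#' @param maxCalls provider-call budget.
#' @return data.frame as in [generateBatch()]; all emitted candidates are
#'   returned (including invalid ones), with attribute `nCalls`.
#' @export
generateN <- function(context, provider, nTotal, batchSize = 10L,
                      dedupe = TRUE, maxCalls = 10L * ceiling(nTotal / batchSize)) {
  stopifnot(nTotal >= 1)
  out <- NULL
  calls <- 0L
  emitted <- 0L
  emittedValid <- 0L
  countKept <- function(df) {
    ok <- df[df$valid, , drop = FALSE]
    if (dedupe) length(unique(ok$smiles)) else nrow(ok)
  }
  while (calls < maxCalls) {
    batch <- generateBatch(context, provider, batchSize, batchIndex = calls)
    calls <- calls + 1L
    emitted <- emitted + nrow(batch)
    emittedValid <- emittedValid + sum(batch$valid)
    out <- if (is.null(out)) batch else rbind(out, batch)
    if (dedupe)
      out <- out[out$valid == FALSE | !duplicated(ifelse(out$valid,
                                                         out$smiles,
                                                         NA_character_),
                                                  incomparables = NA), ,
                 drop = FALSE]
    if (countKept(out) >= nTotal) break
  }
  if (countKept(out) < nTotal)
    amgWarn("call budget (%d) exhausted with %d/%d valid molecules",
            maxCalls, countKept(out), nTotal)
  ## truncate the valid set at nTotal, keep invalid rows for rate accounting
  validIdx <- which(out$valid)
  if (length(validIdx) > nTotal)
    out <- out[-validIdx[seq(nTotal + 1L, length(validIdx))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nCalls") <- calls
  attr(out, "emitted") <- emitted
  attr(out, "emittedValid") <- emittedValid
  out
}

#' Validity rate of a generated set
#'
#' The fraction of emitted candidates that parsed as valid SMILES. For
#' results of [generateN()] the rate is computed over everything the
#' provider emitted (recorded before any truncation of the valid set).
#'
#' @param generated data.frame from [generateBatch()]/[generateN()].
#' @return fraction in \[0, 1\].
#' @export
validityRate <- function(generated) {
  emitted <- attr(generated, "emitted")
  if (!is.null(emitted) && emitted > 0)
    return(attr(generated, "emittedValid") / emitted)
  if (!nrow(generated)) return(NA_real_)
  mean(generated$valid)
}

#' Optimize molecules against an anti-target
#'
#' Appends the input molecules to an anti-target context (built in
#' `optimize_anti_target` mode) and asks the provider for one optimized
#' candidate per input. Outputs pair positionally with inputs so
#' before/after metric deltas can be computed; an invalid or missing output
#' falls back to the input molecule and is flagged.
#'
#' @param molecules non-empty character vector of SMILES to optimize.
#' @param context a [GenerationContext-class] in optimize mode.
#' @param provider a [TextProvider-class].
#' @return data.frame with columns `input`, `optimized` (canonical SMILES),
#'   `valid`, `fallback`.
#' @export
optimizeAgainstAntiTarget <- function(molecules, context, provider) {
  if (!length(molecules))
    amgStop("amg_contract_error", "no molecules to optimize")
  if (context@mode != "optimize_anti_target")
    amgStop("amg_contract_error", "context was not built in optimize mode")
  response <- withRetries(function()
    respondText(provider, list(class = "optimize", prompt = context@prompt,
                               molecules = molecules, context = context)))
  cand <- extractSmilesCandidates(response)
  out <- data.frame(input = as.character(molecules),
                    optimized = NA_character_, valid = FALSE,
                    fallback = TRUE)
  n <- min(nrow(cand), length(molecules))
  if (n > 0) {
    out$optimized[seq_len(n)] <- cand$smiles[seq_len(n)]
    out$valid[seq_len(n)] <- cand$valid[seq_len(n)]
  }
  out$fallback <- !out$valid
  out$optimized[out$fallback] <- canonicalizeSmiles(out$input[out$fallback],
                                                    onInvalid = "na")
  out
}
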