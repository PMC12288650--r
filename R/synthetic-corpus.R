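## Synthetic fixtures: a deterministic molecule pool, assay corpora with
## planted family/relevance/counterscreen structure, and scripted offline
## text providers. Everything is a pure function of its seed, and the
## ground-truth manifest suffices to predict every filter decision.

.scaffoldTemplates <- c(
  "c1ccc(%s)cc1",              # benzene
  "c1ccnc(%s)c1",              # pyridine
  "c1cnc(%s)nc1",              # pyrimidine
  "c1ccc2cc(%s)ccc2c1",        # naphthalene
  "C1CCN(%s)CC1",              # piperidine (N-substituted)
  "O1CCN(%s)CC1",              # morpholine (N-substituted)
  "c1csc(%s)c1",               # thiophene
  "c1coc(%s)c1",               # furan
  "c1ccc2c(c1)c(%s)c[nH]2",    # indole (C3)
  "c1ccc2nc(%s)ccc2c1",        # quinoline
  "c1cc(%s)n[nH]1",            # pyrazole
  "c1cc(%s)ccc1C(=O)Nc1ccccc1" # benzanilide
)

.substituents <- c(
  "F", "Cl", "Br", "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC",
  "N(C)C", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)NC", "S(=O)(=O)N",
  "C(F)(F)F", "CO", "CCO", "CCN", "OC(=O)C", "NC(=O)C", "CCc1ccccc1",
  "CN1CCCC1", "OCC(=O)O")

.namedDrugs <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                 # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",            # caffeine
  "CC(C)Cc1ccc(C(C)C(=O)O)cc1",            # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",                    # paracetamol
  "Nc1ccc(S(N)(=O)=O)cc1",                 # sulfanilamide
  "CCOC(=O)c1ccc(N)cc1",                   # benzocaine
  "OC(=O)c1cccnc1",                        # nicotinic acid
  "NC(=O)c1cccnc1")                        # nicotinamide

#' Deterministic pool of small valid molecules
#'
#' Built by decorating a fixed set of scaffolds with a fixed substituent
#' list (plus a handful of well-known drugs), then canonicalizing, dropping
#' anything unparsable and de-duplicating. Construction guarantees validity
#' and gives controllable scaffold overlap: molecules sharing a scaffold are
#' structurally similar, which the planted-effect fixtures exploit.
#'
#' @param n maximum number of molecules to return (default: all).
#' @return data.frame with columns `smiles` (canonical) and `scaffold`
#'   (integer scaffold id; 0 for the named drugs).
#' @export
moleculePool <- function(n = Inf) {
  hit <- cacheGet("pool", "all")
  if (is.null(hit)) {
    raw <- character(); scaf <- integer()
    for (s in seq_along(.scaffoldTemplates)) {
      cand <- sprintf(.scaffoldTemplates[s], .substituents)
      raw <- c(raw, cand); scaf <- c(scaf, rep(s, length(cand)))
    }
    raw <- c(raw, .namedDrugs); scaf <- c(scaf, rep(0L, length(.namedDrugs)))
    can <- canonicalizeSmiles(raw, onInvalid = "na")
    ok <- !is.na(can) & !duplicated(can)
    hit <- cacheSet("pool", "all",
                    data.frame(smiles = can[ok], scaffold = scaf[ok]))
  }
  head(hit, n)
}

.genericPhrases <- c(
  "dose response confirmation screen measuring luminescent readout",
  "single concentration primary screen in 384 well format",
  "biochemical enzymatic activity assay with purified protein",
  "cell based reporter assay with stable line")

.noiseVocab <- c("buffer", "dmso", "plate", "substrate", "kinetic", "triplicate",
                 "incubation", "signal", "normalized", "hit", "threshold",
                 "automation", "library", "compound", "series")

familySignatureTokens <- function(family) {
  sprintf("fam%02dsig%02d", family, 1:8)
}

familyScaffolds <- function(nFamilies) {
  ids <- seq_along(.scaffoldTemplates)
  split(ids, ((ids - 1L) %% nFamilies) + 1L)
}

familySequence <- function(seed, family, group) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withLocalSeed(deriveSeed(seed, sprintf("seq-%d-%d", family, group)),
                paste(sample(aa, 60, replace = TRUE), collapse = ""))
}

#' Generate a synthetic assay corpus with planted structure
#'
#' Each assay is assigned a target family. Family-specific signature tokens
#' are injected (repeatedly) into the description text so the hashed
#' bag-of-tokens embedding provider separates families by construction.
#' Outcome tables draw active molecules from the family's scaffold slice of
#' the molecule pool and other molecules from the remaining pool, with
#' measurements on a micromolar IC50 scale. A configurable fraction of
#' assays is flagged as counterscreens, recorded both on the record
#' (ground-truth annotation) and in the manifest.
#'
#' @param spec a [CorpusSpec-class].
#' @return list with `records` (named list of [BioAssayRecord-class]),
#'   `manifest` (data.frame: `aid`, `family`, `counterscreen`, `n_actives`,
#'   `table_size`, `uniprot`), and `familyActives` (named list: family ->
#'   planted active SMILES).
#' @export
makeCorpus <- function(spec) {
  validObject(spec)
  pool <- moleculePool()
  scafByFam <- familyScaffolds(spec@nFamilies)
  famActives <- lapply(seq_len(spec@nFamilies), function(f)
    pool$smiles[pool$scaffold %in% scafByFam[[f]]])
  names(famActives) <- as.character(seq_len(spec@nFamilies))
  records <- vector("list", spec@nAssays)
  manifest <- withLocalSeed(spec@seed, {
    rows <- vector("list", spec@nAssays)
    for (i in seq_len(spec@nAssays)) {
      f <- sample.int(spec@nFamilies, 1L)
      cs <- runif(1) < spec@counterscreenFraction
      m <- sample(seq(spec@tableSizeRange[1], spec@tableSizeRange[2]), 1L)
      nAct <- rbinom(1L, m, spec@activesFraction)
      nAct <- min(nAct, length(famActives[[f]]))
      othPool <- pool$smiles[!pool$smiles %in% famActives[[f]]]
      actives <- if (nAct > 0) sample(famActives[[f]], nAct) else character()
      others <- sample(othPool, min(m - nAct, length(othPool)))
      smiles <- c(actives, others)
      outcome <- c(rep("Active", length(actives)),
                   sample(c("Unspecified", "Inactive"), length(others),
                          replace = TRUE))
      hasMeas <- outcome == "Active" | runif(length(smiles)) < 0.5
      ic50 <- signif(exp(rnorm(length(smiles), log(1), 1)) *
                       ifelse(outcome == "Active", 1, 40), 3)
      tab <- data.frame(
        smiles = smiles, outcome = outcome,
        std_type = ifelse(hasMeas, "IC50", NA_character_),
        relation = ifelse(hasMeas, ifelse(outcome == "Inactive", ">", "="),
                          NA_character_),
        value = ifelse(hasMeas, ic50, NA_real_),
        units = ifelse(hasMeas, "uM", NA_character_))
      group <- sample.int(5L, 1L)
      uniprot <- sprintf("P%02d%03d", f, group)
      nNoise <- sample(3:8, 1L)
      description <- paste(
        c(rep(familySignatureTokens(f), 3L),
          sample(.genericPhrases, 1L),
          sample(.noiseVocab, nNoise, replace = TRUE)),
        collapse = " ")
      title <- sprintf("%s screen of family %d receptor (series %d)",
                       if (cs) "Counterscreen selectivity" else "Inhibition",
                       f, i)
      protocol <- sample(.genericPhrases, 1L)
      records[[i]] <- bioAssayRecord(
        aid = i, title = title, description = description,
        protocol = protocol, outcomes = tab,
        target = targetInfo(
          name = sprintf("family %d receptor variant %d", f, group),
          uniprotId = uniprot,
          sequence = familySequence(spec@seed, f, group)),
        counterscreenAnnotation = cs,
        metadata = list(source = "synthetic"))
      rows[[i]] <- data.frame(aid = i, family = f, counterscreen = cs,
                              n_actives = length(actives),
                              table_size = nrow(tab), uniprot = uniprot)
    }
    do.call(rbind, rows)
  })
  list(records = setNames(records, manifest$aid), manifest = manifest,
       familyActives = famActives)
}

#' Build a query for a synthetic family
#'
#' The description carries the family's signature tokens (the same tokens
#' planted in that family's assay descriptions), so retrieval under the
#' hashed bag-of-tokens provider ranks the family's assays on top. Use a
#' family number beyond the corpus's `nFamilies` to obtain a query with no
#' relevant assays.
#'
#' @param family integer family number.
#' @param uniprotId,sequence optional query-protein identifiers.
#' @param desiredActivity desired direction of activity.
#' @return a [ProteinQuery-class].
#' @export
familyQuery <- function(family, uniprotId = NA_character_,
                        sequence = NA_character_,
                        desiredActivity = "inhibition") {
  proteinQuery(
    description = paste(
      c(sprintf("inhibitors of the family %d receptor", family),
        familySignatureTokens(family)), collapse = " "),
    uniprotId = uniprotId, sequence = sequence,
    desiredActivity = desiredActivity)
}

## ---- mock text providers ---------------------------------------------------

#' Scripted deterministic text provider
#'
#' The workhorse mock for the text-generation interface. `handlers` maps a
#' request class (`"keywords"`, `"summarize"`, `"assess"`, `"generate"`,
#' `"optimize"`) to a function `(request, state)` returning the response
#' text; `state` is a provider-owned environment for stateful scripts
#' (cursors, call counters). Requests with an unscripted class raise a
#' contract error.
#'
#' @slot handlers named list of handler functions.
#' @slot state environment shared across calls.
#' @exportClass MockTextProvider
setClass("MockTextProvider", contains = "TextProvider",
         representation(handlers = "list", state = "environment"))

#' @param handlers named list of `(request, state)` functions.
#' @return a `MockTextProvider`.
#' @rdname MockTextProvider-class
#' @export
mockTextProvider <- function(handlers) {
  new("MockTextProvider", handlers = handlers,
      state = new.env(parent = emptyenv()))
}

#' @describeIn MockTextProvider-class dispatch a request to its handler
#' @param provider provider object.
#' @param request request list (`class`, `prompt`, ...).
#' @export
setMethod("respondText", "MockTextProvider", function(provider, request) {
  h <- provider@handlers[[request$class %||% ""]]
  if (is.null(h))
    amgStop("amg_contract_error", "unscripted request class '%s'",
            request$class %||% "<missing>")
  h(request, provider@state)
})

#' Oracle assessment provider for synthetic corpora
#'
#' Reads the ground-truth manifest: an assay is reported relevant when its
#' family equals `queryFamily`, and counterscreen per its planted flag. The
#' summarize handler emits a deterministic canned summary; the keywords
#' handler passes the query description through unchanged.
#'
#' @param manifest manifest data.frame from [makeCorpus()].
#' @param queryFamily the family the query targets.
#' @return a [MockTextProvider-class].
#' @export
oracleTextProvider <- function(manifest, queryFamily) {
  mockTextProvider(list(
    assess = function(request, state) {
      row <- manifest[manifest$aid == aid(request$record), , drop = FALSE]
      if (!nrow(row)) return("RELEVANT: no\nCOUNTERSCREEN: no")
      sprintf("RELEVANT: %s\nCOUNTERSCREEN: %s",
              if (row$family == queryFamily) "yes" else "no",
              if (row$counterscreen) "yes" else "no")
    },
    summarize = function(request, state)
      sprintf("Assay %d tests molecules against a family receptor target.",
              aid(request$record)),
    keywords = function(request, state) request$query@description))
}

#' Pool-backed generation provider
#'
#' Emits molecules from a fixed valid-SMILES pool, without replacement,
#' cycling when the pool is exhausted. In context-biased mode the pool is
#' reordered by decreasing maximum Tanimoto similarity to `contextActives`,
#' emulating in-context learning (generated molecules resemble the context
#' actives); otherwise the pool is deterministically shuffled by `seed`.
#' `corruptEvery = k` replaces every k-th emitted line with an unparsable
#' token, for validity-rate fixtures.
#'
#' @param pool character vector of valid SMILES.
#' @param contextActives optional SMILES to bias toward.
#' @param seed shuffle seed for the unbiased order.
#' @param corruptEvery corrupt every k-th line (0 = never).
#' @return a [MockTextProvider-class] handling `generate` and `optimize`
#'   requests (optimize echoes its input molecules).
#' @export
poolTextProvider <- function(pool, contextActives = NULL, seed = 1L,
                             corruptEvery = 0L) {
  ordered <- if (!is.null(contextActives) && length(contextActives)) {
    sim <- contextSimilarity(pool, contextActives)
    pool[order(-sim, seq_along(pool))]
  } else {
    withLocalSeed(seed, sample(pool))
  }
  provider <- mockTextProvider(list(
    generate = function(request, state) {
      n <- request$n %||% 10L
      if (is.null(state$cursor)) state$cursor <- 0L
      if (is.null(state$emitted)) state$emitted <- 0L
      idx <- ((state$cursor + seq_len(n) - 1L) %% length(ordered)) + 1L
      state$cursor <- state$cursor + n
      lines <- ordered[idx]
      if (corruptEvery > 0L) {
        pos <- state$emitted + seq_len(n)
        bad <- pos %% corruptEvery == 0L
        lines[bad] <- sprintf("not_a_smiles_%d", pos[bad])
      }
      state$emitted <- state$emitted + n
      paste(lines, collapse = "\n")
    },
    optimize = function(request, state)
      paste(request$molecules, collapse = "\n")))
  provider
}

#' Fixed-sequence text provider
#'
#' Pops one canned response per call, regardless of request class; the last
#' response is repeated once the script is exhausted. Used to test failure
#' contracts (e.g. malformed assessment responses).
#'
#' @param responses character vector of responses.
#' @return a [MockTextProvider-class].
#' @export
scriptedTextProvider <- function(responses) {
  force(responses)
  handler <- function(request, state) {
    if (is.null(state$i)) state$i <- 0L
    state$i <- state$i + 1L
    responses[[min(state$i, length(responses))]]
  }
  mockTextProvider(list(keywords = handler, summarize = handler,
                        assess = handler, generate = handler,
                        optimize = handler))
}

#' HTTP chat-completion text provider (untested plumbing)
#'
#' Minimal wrapper around an OpenAI-compatible chat endpoint through the
#' system `curl` binary; offline work uses the mock providers.
#'
#' @slot url endpoint URL.
#' @slot model model name.
#' @slot apiKeyEnv environment variable holding the bearer token.
#' @slot temperature decoding temperature passed through to the endpoint.
#' @exportClass HttpTextProvider
setClass("HttpTextProvider", contains = "TextProvider",
         representation(url = "character", model = "character",
                        apiKeyEnv = "character", temperature = "numeric"))

#' @param url endpoint URL.
#' @param model model name.
#' @param apiKeyEnv environment variable with the token.
#' @param temperature decoding temperature (provider-owned default 1).
#' @return an `HttpTextProvider`.
#' @rdname HttpTextProvider-class
#' @export
httpTextProvider <- function(url, model, apiKeyEnv = "TEXT_API_KEY",
                             temperature = 1) {
  new("HttpTextProvider", url = url, model = model, apiKeyEnv = apiKeyEnv,
      temperature = temperature)
}

#' @describeIn HttpTextProvider-class call the remote endpoint
#' @param provider provider object.
#' @param request request list.
#' @export
setMethod("respondText", "HttpTextProvider", function(provider, request) {
  body <- jsonlite::toJSON(list(
    model = provider@model, temperature = provider@temperature,
    messages = list(list(role = "user", content = request$prompt))),
    auto_unbox = TRUE)
  res <- withRetries(function()
    system2("curl", c("-sS", "-X", "POST", shQuote(provider@url),
                      "-H", shQuote("Content-Type: application/json"),
                      "-H", shQuote(sprintf("Authorization: Bearer %s",
                                            Sys.getenv(provider@apiKeyEnv))),
                      "-d", shQuote(body)),
            stdout = TRUE))
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyVector = FALSE)
  parsed$choices[[1]]$message$content
})
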