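## Embedding providers: a deterministic offline hashed bag-of-tokens
## provider (tests, fixtures) and thin HTTP plumbing for a live endpoint.

#' Deterministic hashed bag-of-tokens embedding provider
#'
#' Each lower-cased token of the input text is hashed (FNV-1a, salted) to a
#' coordinate and a sign; the text embedding is the signed token-count
#' vector. The provider involves no model and no randomness: the same text
#' always maps to the same vector, and texts sharing many tokens are close
#' in cosine similarity. Synthetic corpora plant family-specific signature
#' tokens in assay descriptions, which makes family structure separable
#' under this provider by construction.
#'
#' @slot dim embedding dimension.
#' @slot salt character salt mixed into the hash.
#' @exportClass HashEmbeddingProvider
setClass("HashEmbeddingProvider",
         contains = "EmbeddingProvider",
         representation(dim = "integer", salt = "character"))

#' @param dim embedding dimension.
#' @param salt hash salt (change to decorrelate two providers).
#' @return a `HashEmbeddingProvider`.
#' @rdname HashEmbeddingProvider-class
#' @export
hashEmbeddingProvider <- function(dim = 64L, salt = "amg") {
  new("HashEmbeddingProvider", dim = as.integer(dim), salt = salt,
      tag = sprintf("hash-bow-%s-d%d", salt, dim))
}

#' @describeIn HashEmbeddingProvider-class embed texts deterministically
#' @param provider provider object.
#' @param texts character vector.
#' @export
setMethod("embedText", "HashEmbeddingProvider", function(provider, texts) {
  d <- provider@dim
  out <- matrix(0, length(texts), d)
  for (i in seq_along(texts)) {
    for (tok in tokenizeText(texts[i])) {
      h <- fnv1a32(paste0(provider@salt, "|", tok))
      idx <- (h %% d) + 1L
      sign <- if ((h %/% d) %% 2 == 0) 1 else -1
      out[i, idx] <- out[i, idx] + sign
    }
  }
  out
})

#' HTTP embedding provider (untested plumbing)
#'
#' Minimal wrapper around an OpenAI-compatible embeddings endpoint, invoked
#' through the system `curl` binary. Offline work (all tests and fixtures)
#' uses [hashEmbeddingProvider()] instead.
#'
#' @slot url endpoint URL.
#' @slot model model name sent in the request body.
#' @slot dim expected embedding dimension.
#' @slot apiKeyEnv name of the environment variable holding the API key.
#' @exportClass HttpEmbeddingProvider
setClass("HttpEmbeddingProvider",
         contains = "EmbeddingProvider",
         representation(url = "character", model = "character",
                        dim = "integer", apiKeyEnv = "character"))

#' @param url endpoint URL.
#' @param model model name.
#' @param dim expected dimension.
#' @param apiKeyEnv environment variable with the bearer token.
#' @return an `HttpEmbeddingProvider`.
#' @rdname HttpEmbeddingProvider-class
#' @export
httpEmbeddingProvider <- function(url, model, dim,
                                  apiKeyEnv = "EMBEDDING_API_KEY") {
  new("HttpEmbeddingProvider", url = url, model = model, dim = as.integer(dim),
      apiKeyEnv = apiKeyEnv, tag = sprintf("http-%s-d%d", model, dim))
}

#' @describeIn HttpEmbeddingProvider-class embed via the remote endpoint
#' @param provider provider object.
#' @param texts character vector.
#' @export
setMethod("embedText", "HttpEmbeddingProvider", function(provider, texts) {
  body <- jsonlite::toJSON(list(model = provider@model, input = texts),
                           auto_unbox = TRUE)
  res <- withRetries(function()
    system2("curl", c("-sS", "-X", "POST", shQuote(provider@url),
                      "-H", shQuote("Content-Type: application/json"),
                      "-H", shQuote(sprintf("Authorization: Bearer %s",
                                            Sys.getenv(provider@apiKeyEnv))),
                      "-d", shQuote(body)),
            stdout = TRUE))
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""))
  mat <- do.call(rbind, parsed$data$embedding)
  if (ncol(mat) != provider@dim)
    amgStop("amg_backend_error", "endpoint returned dimension %d, expected %d",
            ncol(mat), provider@dim)
  mat
})

## Retry a backend call a few times before giving up.
withRetries <- function(fn, times = 3L, waitSeconds = 0.5) {
  for (i in seq_len(times)) {
    res <- tryCatch(fn(), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (i < times) Sys.sleep(waitSeconds)
  }
  amgStop("amg_backend_error", "backend failed after %d attempts: %s",
          times, conditionMessage(res))
}

## Text used to embed a record: all descriptive fields, serialized compactly.
recordEmbeddingText <- function(record) {
  paste(record@title, record@description, record@protocol,
        if (!is.null(record@target)) record@target@name else "",
        sep = "\n")
}

#' Embed a protein query
#'
#' Optionally condenses the query description to keywords through a text
#' provider (request class `"keywords"`) before embedding; the keyword step
#' is bypassable and off by default, in which case the raw description is
#' embedded.
#'
#' @param query a [ProteinQuery-class].
#' @param provider an [EmbeddingProvider-class].
#' @param textProvider optional [TextProvider-class] for keyword extraction.
#' @param useKeywords condense the description first?
#' @return numeric embedding vector of length `dim`.
#' @export
embedQuery <- function(query, provider, textProvider = NULL,
                       useKeywords = FALSE) {
  text <- query@description
  if (useKeywords) {
    if (is.null(textProvider))
      amgStop("amg_contract_error",
              "useKeywords = TRUE requires a text provider")
    text <- respondText(textProvider, list(
      class = "keywords",
      prompt = paste("Extract the key protein/phenotype terms from:", text),
      query = query))
  }
  as.numeric(embedText(provider, text))
}
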