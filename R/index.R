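## Exact in-memory vector index: cosine similarity and top-k retrieval.

#' Cosine similarity of two embedding vectors
#'
#' `u . v / (|u| |v|)`. Embeddings are stored unnormalized; normalization
#' happens here.
#'
#' @param u,v numeric vectors of equal dimension, both nonzero.
#' @return similarity in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v))
    amgStop("amg_contract_error", "dimension mismatch: %d vs %d",
            length(u), length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    amgStop("amg_degenerate_error", "cosine similarity of a zero vector")
  sum(u * v) / (nu * nv)
}

#' Build an exact vector index over an assay corpus
#'
#' Embeds every record's descriptive text (title, description, protocol,
#' target name) with the given provider. All vectors share one dimension,
#' fixed at build time.
#'
#' @param corpus named list of [BioAssayRecord-class] objects.
#' @param provider an [EmbeddingProvider-class].
#' @return an [AssayIndex-class].
#' @export
buildAssayIndex <- function(corpus, provider) {
  if (!length(corpus)) amgStop("amg_empty_corpus", "corpus is empty")
  texts <- vapply(corpus, recordEmbeddingText, character(1))
  vectors <- embedText(provider, texts)
  new("AssayIndex", aids = unname(vapply(corpus, aid, integer(1))),
      vectors = unname(vectors), dim = ncol(vectors),
      providerTag = provider@tag)
}

#' Retrieve the top-k most similar assays
#'
#' Ranks all indexed assays by cosine similarity to the query embedding and
#' returns the k best (all, if fewer exist). Ties are broken by ascending
#' aid, making retrieval fully deterministic.
#'
#' @param index an [AssayIndex-class].
#' @param query numeric query embedding of the index's dimension.
#' @param k number of assays to return.
#' @return data.frame with columns `aid` and `similarity`, ordered by
#'   decreasing similarity.
#' @export
topK <- function(index, query, k) {
  if (!length(index@aids)) amgStop("amg_empty_corpus", "index is empty")
  stopifnot(k >= 1)
  if (length(query) != index@dim)
    amgStop("amg_contract_error", "query dimension %d, index dimension %d",
            length(query), index@dim)
  qn <- sqrt(sum(query^2))
  if (qn == 0) amgStop("amg_degenerate_error", "query embedding is all-zero")
  rn <- sqrt(rowSums(index@vectors^2))
  if (any(rn == 0))
    amgStop("amg_degenerate_error", "index contains an all-zero embedding")
  sim <- as.vector(index@vectors %*% query) / (rn * qn)
  ord <- order(-sim, index@aids)
  keep <- head(ord, min(k, length(ord)))
  data.frame(aid = index@aids[keep], similarity = sim[keep])
}

#' Persist / load an assay index
#'
#' The on-disk format is a directory with a versioned JSON manifest
#' (`manifest.json`: format version, dimension, provider tag, aid order) and
#' a CSV matrix of vectors (`vectors.csv`, one row per aid).
#'
#' @param index an [AssayIndex-class].
#' @param dir directory path.
#' @return `saveAssayIndex`: `dir`, invisibly; `loadAssayIndex`: the index.
#' @export
saveAssayIndex <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(format_version = 1L, dim = index@dim, provider = index@providerTag,
         aids = index@aids),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(index@vectors, file.path(dir, "vectors.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname saveAssayIndex
#' @export
loadAssayIndex <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version), 1L))
    amgStop("amg_schema_error", "unsupported index format version %s",
            manifest$format_version)
  vectors <- as.matrix(utils::read.table(file.path(dir, "vectors.csv"),
                                         sep = ",", header = FALSE))
  dimnames(vectors) <- NULL
  new("AssayIndex", aids = as.integer(manifest$aids), vectors = vectors,
      dim = as.integer(manifest$dim), providerTag = manifest$provider)
}
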