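## Readers and writers for assay records (JSON / JSON-lines), outcome tables
## (CSV) and molecule lists (SMILES files).

.outcomeSynonyms <- c(
  active = "Active", inactive = "Inactive", unspecified = "Unspecified",
  inconclusive = "Unspecified", probe = "Active")

#' Normalize activity outcome labels
#'
#' Labels are matched case-insensitively; a documented synonym map folds
#' common repository variants (`"inconclusive"` to `Unspecified`, `"probe"`
#' to `Active`) onto the three-label scheme.
#'
#' @param labels character vector of raw labels.
#' @return character vector over `Active`, `Unspecified`, `Inactive`.
#' @export
normalizeOutcomeLabels <- function(labels) {
  key <- tolower(trimws(as.character(labels)))
  out <- .outcomeSynonyms[key]
  bad <- which(is.na(out))
  if (length(bad))
    amgStop("amg_schema_error", "unrecognized outcome label '%s' in row %d",
            labels[bad[1]], bad[1])
  unname(out)
}

#' Construct a BioAssayRecord
#'
#' @param aid positive integer assay identifier.
#' @param title,description,protocol text fields.
#' @param outcomes data.frame with at least `smiles` and `outcome` columns;
#'   measurement columns (`std_type`, `relation`, `value`, `units`) are
#'   optional and `NA`-filled when absent. Outcome labels are normalized.
#' @param target optional [TargetInfo-class].
#' @param counterscreenAnnotation optional ground-truth counterscreen flag.
#' @param metadata list of extra fields to preserve.
#' @return a [BioAssayRecord-class].
#' @export
bioAssayRecord <- function(aid, title = "", description = "", protocol = "",
                           outcomes = emptyOutcomeTable(), target = NULL,
                           counterscreenAnnotation = NA, metadata = list()) {
  outcomes <- as.data.frame(outcomes)
  if (nrow(outcomes)) {
    outcomes$outcome <- normalizeOutcomeLabels(outcomes$outcome)
    for (col in c("std_type", "relation", "units"))
      if (is.null(outcomes[[col]])) outcomes[[col]] <- NA_character_
    if (is.null(outcomes$value)) outcomes$value <- NA_real_
    outcomes$value <- as.numeric(outcomes$value)
  } else {
    outcomes <- emptyOutcomeTable()
  }
  rownames(outcomes) <- NULL
  outcomes <- outcomes[c("smiles", "outcome", "std_type", "relation",
                         "value", "units")]
  new("BioAssayRecord", aid = as.integer(aid), title = title,
      description = description, protocol = protocol, target = target,
      outcomes = outcomes,
      counterscreenAnnotation = as.logical(counterscreenAnnotation),
      metadata = metadata)
}

.recordKeys <- c("aid", "title", "description", "protocol", "outcomes",
                 "target", "is_counterscreen_annotation")

#' Parse one assay record from JSON
#'
#' The JSON schema has required keys `aid`, `title`, `description`,
#' `protocol`, `outcomes` and optional keys `target` and
#' `is_counterscreen_annotation`; unknown keys are preserved in the record's
#' metadata bag and survive a write/parse round trip.
#'
#' @param text a JSON document (character scalar).
#' @return a [BioAssayRecord-class].
#' @export
parseBioAssayJson <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyDataFrame = TRUE),
                  error = function(e)
                    amgStop("amg_parse_error", "malformed JSON: %s",
                            conditionMessage(e)))
  need <- c("aid", "title", "description", "protocol", "outcomes")
  if (is.null(doc$aid))
    amgStop("amg_schema_error", "record is missing required key 'aid'")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    amgStop("amg_schema_error", "record %s is missing required key(s): %s",
            doc$aid, paste(miss, collapse = ", "))
  out <- doc$outcomes
  if (is.null(out) || length(out) == 0L) out <- emptyOutcomeTable()
  if (!is.data.frame(out))
    amgStop("amg_schema_error", "outcomes of record %s is not a table", doc$aid)
  target <- NULL
  if (!is.null(doc$target))
    target <- targetInfo(
      name = doc$target$name %||% "",
      uniprotId = doc$target$uniprot_id %||% NA_character_,
      sequence = doc$target$sequence %||% NA_character_)
  meta <- doc[setdiff(names(doc), .recordKeys)]
  bioAssayRecord(
    aid = doc$aid, title = doc$title, description = doc$description,
    protocol = doc$protocol, outcomes = out, target = target,
    counterscreenAnnotation = doc$is_counterscreen_annotation %||% NA,
    metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

recordToList <- function(record) {
  out <- list(
    aid = record@aid, title = record@title, description = record@description,
    protocol = record@protocol, outcomes = record@outcomes)
  if (!is.null(record@target))
    out$target <- list(uniprot_id = record@target@uniprotId,
                       name = record@target@name,
                       sequence = record@target@sequence)
  if (!is.na(record@counterscreenAnnotation))
    out$is_counterscreen_annotation <- record@counterscreenAnnotation
  c(out, record@metadata)
}

#' Serialize an assay record to JSON
#'
#' Inverse of [parseBioAssayJson()]: `parseBioAssayJson(writeBioAssayJson(x))`
#' reproduces `x` field for field.
#'
#' @param record a [BioAssayRecord-class].
#' @return character scalar of JSON.
#' @export
writeBioAssayJson <- function(record) {
  as.character(jsonlite::toJSON(recordToList(record), auto_unbox = TRUE,
                                digits = NA, na = "null", null = "null"))
}

#' Read / write an assay corpus as JSON-lines
#'
#' One record per line. A corpus is a list of [BioAssayRecord-class] objects
#' named by their aid; aids must be unique.
#'
#' @param path file path.
#' @return `readAssayCorpus`: named list of records.
#' @export
readAssayCorpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(lines, parseBioAssayJson)
  aids <- vapply(records, aid, integer(1))
  if (anyDuplicated(aids))
    amgStop("amg_schema_error", "duplicate aid %d in corpus",
            aids[anyDuplicated(aids)])
  setNames(records, aids)
}

#' @rdname readAssayCorpus
#' @param corpus list of [BioAssayRecord-class] objects.
#' @return `writeAssayCorpus`: the path, invisibly.
#' @export
writeAssayCorpus <- function(corpus, path) {
  writeLines(vapply(corpus, writeBioAssayJson, character(1)), path)
  invisible(path)
}

#' Read / write an outcome table as CSV
#'
#' Column layout: `smiles,outcome,std_type,relation,value,units`.
#'
#' @param path file path.
#' @return `readOutcomeCsv`: a normalized outcome data.frame.
#' @export
readOutcomeCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""),
                        colClasses = c(value = "numeric"))
  df$outcome <- normalizeOutcomeLabels(df$outcome)
  ok <- validateOutcomeTable(df)
  if (!isTRUE(ok)) amgStop("amg_schema_error", "%s", ok)
  df
}

#' @rdname readOutcomeCsv
#' @param outcomes outcome data.frame.
#' @return `writeOutcomeCsv`: the path, invisibly.
#' @export
writeOutcomeCsv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write SMILES files
#'
#' One molecule per line, optionally followed by a tab-separated name.
#'
#' @param path file path.
#' @return `readSmilesFile`: character vector of SMILES, named when the file
#'   carries names.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else "", character(1))
  if (any(nzchar(nms))) names(smi) <- nms
  smi
}

#' @rdname readSmilesFile
#' @param smiles character vector (names, if any, written as a second column).
#' @return `writeSmilesFile`: the path, invisibly.
#' @export
writeSmilesFile <- function(smiles, path) {
  lines <- if (is.null(names(smiles))) as.character(smiles)
           else paste(smiles, names(smiles), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
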