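## Drug-likeness and synthetic-accessibility scores, computed with RDKit
## through the bundled helper script (inst/python/mol_metrics.py). RDKit is
## the standard implementation of both metrics; calls are batched (one
## interpreter start per molecule list) and memoised.

pythonBinary <- function() {
  p <- Sys.getenv("AMG_PYTHON", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3"))
    if (nzchar(Sys.which(cand))) return(Sys.which(cand))
  amgStop("amg_backend_error", "no python interpreter found on PATH")
}

#' Drug-likeness and synthetic-accessibility scores
#'
#' Computes the quantitative estimate of drug-likeness (QED, in \[0, 1\],
#' higher is more drug-like) and the Ertl synthetic-accessibility score for
#' each molecule, using RDKit. The raw SA score lives on a 1-10 scale where
#' 10 is hardest to synthesize; `sa_norm = 1 - (sa_raw - 1)/9` maps it to
#' \[0, 1\] with 0 the most difficult.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `smiles`, `qed`, `sa_raw`, `sa_norm`,
#'   `size` (heavy atoms); `NA` rows for unparsable SMILES.
#' @export
moleculeProperties <- function(smiles) {
  smiles <- as.character(smiles)
  key <- function(s) cacheGet("qed", s)
  todo <- unique(smiles[vapply(smiles, function(s) is.null(key(s)), logical(1))])
  if (length(todo)) {
    res <- system2(pythonBinary(),
                   shQuote(system.file("python", "mol_metrics.py",
                                       package = "AssayMolGen", mustWork = TRUE)),
                   input = todo, stdout = TRUE, stderr = FALSE)
    if (length(res) != length(todo))
      amgStop("amg_backend_error",
              "property backend returned %d rows for %d molecules",
              length(res), length(todo))
    for (i in seq_along(todo)) {
      f <- suppressWarnings(as.numeric(strsplit(res[i], "\t")[[1]]))
      cacheSet("qed", todo[i], f)
    }
  }
  rows <- t(vapply(smiles, function(s) cacheGet("qed", s), numeric(3)))
  data.frame(smiles = smiles, qed = rows[, 1], sa_raw = rows[, 2],
             sa_norm = 1 - (rows[, 2] - 1) / 9, size = as.integer(rows[, 3]),
             row.names = NULL)
}
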