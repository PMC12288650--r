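## SMILES-level chemistry, backed by OpenBabel through ChemmineR/ChemmineOB.
## Circular fingerprints (ECFP4) are expensive to compute, so every derived
## quantity is memoised in a namespace-level cache keyed by the input string.

.chemCache <- new.env(parent = emptyenv())

cacheGet <- function(kind, key) {
  k <- paste0(kind, "\r", key)
  if (exists(k, envir = .chemCache, inherits = FALSE))
    get(k, envir = .chemCache, inherits = FALSE)
  else NULL
}

cacheSet <- function(kind, key, value) {
  assign(paste0(kind, "\r", key), value, envir = .chemCache)
  value
}

canonicalizeOne <- function(smi) {
  hit <- cacheGet("can", smi)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste(smi, "m"))),
    error = function(e) "")
  can <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(can) || !nzchar(can)) can <- NA_character_
  cacheSet("can", smi, can)
}

#' Canonicalize SMILES strings
#'
#' Maps every spelling of a molecule to a single canonical SMILES string, so
#' that duplicates can be detected by string equality. Canonicalization is
#' idempotent: applying it to its own output returns the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @param onInvalid `"error"` to fail on the first unparsable string,
#'   `"na"` to return `NA` for unparsable entries.
#' @return character vector of canonical SMILES, same length as `smiles`.
#' @examples
#' canonicalizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonicalizeSmiles <- function(smiles, onInvalid = c("error", "na")) {
  onInvalid <- match.arg(onInvalid)
  out <- vapply(as.character(smiles), canonicalizeOne, character(1),
                USE.NAMES = FALSE)
  if (onInvalid == "error" && anyNA(out)) {
    bad <- smiles[is.na(out)][1]
    amgStop("amg_validity_error", "invalid SMILES: '%s'", bad)
  }
  out
}

#' Test whether SMILES strings are parsable
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
isValidSmiles <- function(smiles) {
  !is.na(canonicalizeSmiles(smiles, onInvalid = "na"))
}

#' Count heavy (non-hydrogen) atoms
#'
#' Molecule size is tracked as the number of heavy atoms, both for pruning
#' oversized context molecules and as an evaluation metric (docking scores
#' correlate with atom count).
#'
#' @param smiles character vector of valid SMILES.
#' @return integer vector of heavy-atom counts.
#' @examples
#' heavyAtomCount(c("C", "c1ccccc1"))  # 1, 6
#' @export
heavyAtomCount <- function(smiles) {
  smiles <- as.character(smiles)
  out <- integer(length(smiles))
  miss <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    hit <- cacheGet("hac", smiles[i])
    if (is.null(hit)) miss[i] <- TRUE else out[i] <- hit
  }
  if (any(miss)) {
    todo <- unique(smiles[miss])
    can <- canonicalizeSmiles(todo)  # errors on invalid input
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(setNames(can, paste0("m", seq_along(can)))))
    counts <- ChemmineR::atomcount(sdf)
    n <- vapply(counts, function(tab) sum(tab[names(tab) != "H"]), numeric(1))
    if (length(n) != length(todo))
      amgStop("amg_validity_error", "atom counting failed for %d molecule(s)",
              length(todo) - length(n))
    for (i in seq_along(todo)) cacheSet("hac", todo[i], as.integer(n[i]))
    for (i in which(miss)) out[i] <- cacheGet("hac", smiles[i])
  }
  out
}

ecfp4One <- function(can) {
  hit <- cacheGet("fp", can)
  if (!is.null(hit)) return(hit)
  m <- ChemmineOB::forEachMol("SMILES", paste(can, "m"), function(mol)
    ChemmineOB::fingerprint_OB(list(mol), "ECFP4"))[[1]]
  if (is.matrix(m)) m <- m[1, ]
  cacheSet("fp", can, as.integer(m))
}

#' Circular (Morgan-type) fingerprints
#'
#' Radius-2 circular fingerprints (ECFP4) computed with OpenBabel and folded
#' to `nbits` bits. These are the fingerprints behind the diversity and
#' context-similarity metrics.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits number of bits after folding (default 2048).
#' @return binary integer matrix, one row per molecule, `nbits` columns; rows
#'   named by the input SMILES.
#' @export
morganFingerprints <- function(smiles, nbits = 2048L) {
  can <- canonicalizeSmiles(smiles)
  raw <- t(vapply(can, ecfp4One, integer(4096L)))
  if (nbits >= ncol(raw)) {
    fp <- raw
  } else {
    stopifnot(ncol(raw) %% nbits == 0)
    fp <- matrix(0L, nrow(raw), nbits)
    for (j in seq_len(ncol(raw) / nbits))
      fp <- pmax(fp, raw[, ((j - 1) * nbits + 1):(j * nbits), drop = FALSE])
  }
  rownames(fp) <- smiles
  fp
}

#' Tanimoto similarity between fingerprint sets
#'
#' @param fpA,fpB binary fingerprint matrices (rows = molecules) with equal
#'   column counts, as returned by [morganFingerprints()].
#' @return matrix of pairwise Tanimoto similarities, `nrow(fpA)` by
#'   `nrow(fpB)`. Two empty fingerprints have similarity 0 by convention.
#' @export
tanimotoSimilarity <- function(fpA, fpB) {
  stopifnot(ncol(fpA) == ncol(fpB))
  inter <- fpA %*% t(fpB)
  a <- rowSums(fpA); b <- rowSums(fpB)
  uni <- outer(a, b, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(fpA), rownames(fpB))
  sim
}
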