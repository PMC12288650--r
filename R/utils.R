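## Internal utilities: deterministic hashing, scoped RNG, token heuristics.

#' @import methods
#' @importFrom stats median qnorm runif rnorm rbinom setNames
#' @importFrom utils head modifyList
NULL

## 32-bit FNV-1a over the UTF-8 bytes of a string. R has no integer type wide
## enough for the 32-bit multiply, so it is split into 16-bit halves and
## recombined mod 2^32; all intermediates stay below 2^53 and remain exact in
## doubles.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  prime <- 16777619
  mod <- 4294967296
  h <- 2166136261
  for (byte in utf8ToInt(enc2utf8(x))) {
    ## xor on values < 2^32 via 16-bit halves (bitwXor needs 32-bit ints)
    hi <- h %/% 65536; lo <- h %% 65536
    bhi <- byte %/% 65536; blo <- byte %% 65536
    h <- bitwXor(hi, bhi) * 65536 + bitwXor(lo, blo)
    ## multiply mod 2^32, again in halves
    h <- ((h %% 65536) * prime + ((h %/% 65536) * prime %% 65536) * 65536) %% mod
  }
  h
}

## Hex digest used for prompt/context provenance.
fnvDigest <- function(x) {
  ## two passes with different salts to get 64 hex-stable bits
  hex <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536),
                             as.integer(h %% 65536))
  paste0(hex(fnv1a32(paste0("a|", x))), hex(fnv1a32(paste0("b|", x))))
}

## Map a string deterministically to a uniform deviate in (0, 1).
hashUnit <- function(x) (fnv1a32(x) + 0.5) / 4294967296

## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## stream. Generator kinds are pinned so results are stable across platforms.
withLocalSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

## Derive a child seed from a parent seed and a label, keeping it < 2^31.
deriveSeed <- function(seed, label) {
  (as.numeric(seed) %% 65536) * 32749 + fnv1a32(paste0(label, ":", seed)) %% 32749
}

## Crude prompt-size heuristic: ~4 characters per token.
estimateTokens <- function(text) ceiling(nchar(text, type = "bytes") / 4)

## Lower-cased alphanumeric tokens of a free-text field.
tokenizeText <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9_]+")[[1]]
  toks[nzchar(toks)]
}

amgStop <- function(class, msg, ...) {
  stop(structure(class = c(class, "amg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

amgWarn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)
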