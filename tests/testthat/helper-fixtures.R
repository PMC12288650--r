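## Shared fixtures, memoised for the test session. All fixture molecules come
## from the deterministic pool, so expensive per-molecule chemistry
## (fingerprints, atom counts) is computed once and cached.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

fixPool <- function() memoFixture("pool", function() moleculePool())

fixCorpus <- function(seed = 7L, nAssays = 30L, nFamilies = 3L,
                      counterscreenFraction = 0.15) {
  key <- sprintf("corpus-%d-%d-%d-%s", seed, nAssays, nFamilies,
                 counterscreenFraction)
  memoFixture(key, function()
    makeCorpus(corpusSpec(nAssays = nAssays, nFamilies = nFamilies,
                          counterscreenFraction = counterscreenFraction,
                          seed = seed)))
}

## A random outcome table drawn from the pool: n rows, roughly pActive of
## them Active, deterministic in seed.
randomOutcomeTable <- function(n, pActive, seed) {
  pool <- fixPool()$smiles
  withr::with_seed(seed, {
    smiles <- sample(pool, n, replace = FALSE)
    active <- runif(n) < pActive
    data.frame(
      smiles = smiles,
      outcome = ifelse(active, "Active",
                       sample(c("Unspecified", "Inactive"), n, replace = TRUE)),
      std_type = NA_character_, relation = NA_character_,
      value = NA_real_, units = NA_character_)
  })
}

## Independent heavy-atom oracle: count atoms from the molecular formula
## (OpenBabel-computed), excluding hydrogens.
formulaHeavyAtoms <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    setNames(canonicalizeSmiles(smiles), paste0("m", seq_along(smiles)))))
  props <- ChemmineR::propOB(sdf)
  vapply(props$formula, function(f) {
    parts <- regmatches(f, gregexpr("[A-Z][a-z]?\\d*", f))[[1]]
    total <- 0L
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      ct <- gsub("[^0-9]", "", p)
      ct <- if (nzchar(ct)) as.integer(ct) else 1L
      if (el != "H") total <- total + ct
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}
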