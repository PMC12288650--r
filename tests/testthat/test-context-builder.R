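poolTable <- function(n, nActive, seed = 1L) {
  pool <- fixPool()$smiles
  withr::with_seed(seed, {
    smiles <- sample(pool, n)
    data.frame(smiles = smiles,
               outcome = c(rep("Active", nActive),
                           sample(c("Unspecified", "Inactive"), n - nActive,
                                  replace = TRUE)),
               std_type = NA_character_, relation = NA_character_,
               value = NA_real_, units = NA_character_)
  })
}

test_that("size pruning is strict above the ceiling and inclusive at it", {
  chain45 <- strrep("C", 45)   # exactly 45 heavy atoms
  chain46 <- strrep("C", 46)
  tab <- data.frame(smiles = c(chain45, chain46, "CCO"),
                    outcome = c("Active", "Active", "Inactive"),
                    std_type = NA_character_, relation = NA_character_,
                    value = NA_real_, units = NA_character_)
  out <- pruneBySize(tab, 45L)
  expect_identical(out$smiles, c(chain45, "CCO"))
  ## empty input passes through
  expect_identical(nrow(pruneBySize(tab[0, ], 45L)), 0L)
})

test_that("size pruning equals a direct predicate scan and drops invalid rows", {
  tab <- poolTable(40, 10, seed = 8)
  out <- pruneBySize(tab, 15L)
  expect_identical(out$smiles,
                   tab$smiles[heavyAtomCount(tab$smiles) <= 15L])
  tab2 <- rbind(tab, data.frame(smiles = "b0gus(", outcome = "Active",
                                std_type = NA_character_,
                                relation = NA_character_, value = NA_real_,
                                units = NA_character_))
  expect_warning(out2 <- pruneBySize(tab2, 15L), regexp = "invalid SMILES")
  expect_identical(out2$smiles, out$smiles)
  expect_identical(attr(out2, "invalidDropped"), 1L)
})

test_that("molecule selection follows the class-balance rules", {
  ## oversupply in both classes: nMol of each
  tab <- poolTable(42, 12, seed = 3)
  sel <- selectMolecules(tab, nMol = 8L, seed = 5L)
  expect_identical(nrow(sel@actives), 8L)
  expect_identical(nrow(sel@others), 8L)
  expect_false(sel@allMode)
  expect_true(all(sel@actives$outcome == "Active"))
  expect_true(all(sel@others$outcome != "Active"))
  ## undersupply takes everything
  small <- poolTable(6, 3, seed = 4)
  sel2 <- selectMolecules(small, nMol = 8L, seed = 5L)
  expect_identical(nrow(sel2@actives), 3L)
  expect_identical(nrow(sel2@others), 3L)
  ## no actives: all-mode, capped at 2 * nMol
  noAct <- poolTable(20, 0, seed = 6)
  sel3 <- selectMolecules(noAct, nMol = 8L, seed = 5L)
  expect_true(sel3@allMode)
  expect_identical(nrow(sel3@actives), 0L)
  expect_identical(nrow(sel3@others), 16L)
  ## empty table is a contract error
  expect_error(selectMolecules(noAct[0, ], 8L, 1L),
               class = "amg_contract_error")
})

test_that("selection is a pure function of the seed", {
  tab <- poolTable(60, 20, seed = 9)
  a <- selectMolecules(tab, 8L, seed = 42L)
  b <- selectMolecules(tab, 8L, seed = 42L)
  expect_identical(a@actives, b@actives)
  expect_identical(a@others, b@others)
  differing <- vapply(1:20, function(s)
    !identical(selectMolecules(tab, 8L, seed = s)@actives, a@actives),
    logical(1))
  expect_true(mean(differing) > 0.5)  # different seeds overwhelmingly differ
})

test_that("table rendering is deterministic with actives first", {
  tab <- data.frame(
    smiles = c("CCO", "c1ccccc1", "CCN"),
    outcome = c("Inactive", "Active", "Unspecified"),
    std_type = c("IC50", "IC50", NA), relation = c(">", "=", NA),
    value = c(40, 0.25, NA), units = c("uM", "uM", NA))
  txt <- renderOutcomeTable(tab)
  expect_identical(txt, paste(
    "smiles | outcome | measurement",
    "c1ccccc1 | Active | IC50 = 0.25 uM",
    "CCO | Inactive | IC50 > 40 uM",
    "CCN | Unspecified |",
    sep = "\n"))
  expect_identical(renderOutcomeTable(tab), txt)
  ## one-row table: header plus one line
  one <- tab[2, ]
  expect_identical(length(strsplit(renderOutcomeTable(one), "\n")[[1]]), 2L)
})

test_that("summaries pass through the provider and flag counterscreens", {
  corp <- fixCorpus()
  rec <- corp$records[[1]]
  q <- familyQuery(1)
  canned <- mockTextProvider(list(
    summarize = function(request, state) "A concise assay summary."))
  expect_identical(summarizeAssay(rec, q, canned),
                   "A concise assay summary.")
  s <- summarizeAssay(rec, q, canned, counterscreen = TRUE)
  expect_match(s, "active molecules should be avoided")
  expect_identical(summarizeAssay(rec, q, canned),
                   summarizeAssay(rec, q, canned))
})

test_that("prompt assembly is deterministic and degrades to description-only", {
  q <- familyQuery(1)
  ctx0 <- buildPrompt(q, list(), batchSize = 10L)
  expect_identical(length(ctx0@blocks), 0L)
  expect_match(ctx0@prompt, "Query target")
  expect_match(ctx0@prompt, "propose 10 new candidate molecules")
  ## with blocks: stable across calls, blocks in similarity order
  corp <- fixCorpus()
  cfg <- retrievalConfig(k = 30L, seed = 2L)
  emb <- hashEmbeddingProvider(64)
  idx <- buildAssayIndex(corp$records, emb)
  oracle <- oracleTextProvider(corp$manifest, 1)
  ret <- retrieveAssays(q, idx, corp$records, cfg, emb, oracle)
  blocks <- buildContextBlocks(ret$selected, corp$records, q, cfg, oracle)
  ctx1 <- buildPrompt(q, blocks)
  ctx2 <- buildPrompt(q, blocks)
  expect_identical(ctx1@prompt, ctx2@prompt)
  for (b in blocks) expect_match(ctx1@prompt, b$assessment@summary,
                                 fixed = TRUE)
})

test_that("optimize mode embeds the molecules to optimize verbatim", {
  q <- familyQuery(1)
  mols <- head(fixPool()$smiles, 5L)
  ctx <- buildPrompt(q, list(), mode = "optimize_anti_target",
                     optimizationTargets = mols)
  for (m in mols) expect_match(ctx@prompt, m, fixed = TRUE)
  expect_error(buildPrompt(q, list(), mode = "optimize_anti_target"),
               class = "amg_contract_error")
})

test_that("over-budget prompts drop the lowest-ranked blocks with a warning", {
  q <- familyQuery(1)
  corp <- fixCorpus()
  cfg <- retrievalConfig(k = 30L, seed = 2L)
  emb <- hashEmbeddingProvider(64)
  idx <- buildAssayIndex(corp$records, emb)
  oracle <- oracleTextProvider(corp$manifest, 1)
  ret <- retrieveAssays(q, idx, corp$records, cfg, emb, oracle)
  blocks <- buildContextBlocks(ret$selected, corp$records, q, cfg, oracle)
  full <- buildPrompt(q, blocks)
  budget <- ceiling(nchar(full@prompt, type = "bytes") / 4) - 50L
  expect_warning(trimmed <- buildPrompt(q, blocks, tokenBudget = budget),
                 regexp = "token budget")
  expect_lt(length(trimmed@blocks), length(blocks))
})

test_that("counterscreen actives surface as avoid-examples in the prompt", {
  corp <- fixCorpus()
  csAids <- corp$manifest$aid[corp$manifest$counterscreen &
                                corp$manifest$family == 1 &
                                corp$manifest$n_actives > 0]
  expect_gt(length(csAids), 0)  # the fixture seed plants at least one
  sel <- data.frame(aid = csAids[1], similarity = 0.9, counterscreen = TRUE)
  cfg <- retrievalConfig(seed = 3L)
  oracle <- oracleTextProvider(corp$manifest, 1)
  blocks <- buildContextBlocks(sel, corp$records, familyQuery(1), cfg, oracle)
  avoid <- attr(blocks, "avoidMolecules")
  expect_gt(length(avoid), 0)
  ctx <- buildPrompt(familyQuery(1), blocks)
  expect_match(ctx@prompt, "Avoid molecules similar", fixed = TRUE)
  expect_identical(ctx@avoidMolecules, avoid)
})
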