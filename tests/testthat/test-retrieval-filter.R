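## Small helpers building retrieval inputs from a fixture corpus.

rankedResults <- function(corp, family = 1L, emb = hashEmbeddingProvider(64)) {
  idx <- buildAssayIndex(corp$records, emb)
  topK(idx, embedQuery(familyQuery(family), emb), k = length(corp$records))
}

test_that("assays sharing the query accession are excluded", {
  corp <- fixCorpus()
  res <- rankedResults(corp)
  shared <- corp$manifest$uniprot[1]
  q <- familyQuery(1, uniprotId = shared)
  out <- excludeQueryTarget(res, corp$records, q)
  expectGone <- corp$manifest$aid[corp$manifest$uniprot == shared]
  expect_false(any(expectGone %in% out$aid))
  expect_identical(nrow(out), nrow(res) - length(expectGone))
  ## order of survivors preserved
  expect_identical(out$aid, res$aid[!res$aid %in% expectGone])
  ## no-op without an accession
  expect_identical(excludeQueryTarget(res, corp$records, familyQuery(1)), res)
})

test_that("minimum-table-size filter is boundary-inclusive with the no-actives escalation", {
  mkRec <- function(aidv, n, nActive) {
    pool <- fixPool()$smiles
    bioAssayRecord(aid = aidv, title = "t", description = "d", protocol = "p",
                   outcomes = data.frame(
                     smiles = pool[seq_len(n)],
                     outcome = c(rep("Active", nActive),
                                 rep("Inactive", n - nActive))))
  }
  nMol <- 8L
  recs <- list(
    `1` = mkRec(1, 4, 2),    # exactly minMolNum -> kept
    `2` = mkRec(2, 3, 1),    # below minMolNum -> dropped
    `3` = mkRec(3, 15, 0),   # no actives, 2*nMol - 1 -> dropped
    `4` = mkRec(4, 16, 0),   # no actives, exactly 2*nMol -> kept
    `5` = mkRec(5, 16, 3))   # actives present, big enough -> kept
  res <- data.frame(aid = 1:5, similarity = seq(0.9, 0.5, by = -0.1))
  out <- filterMinMolecules(res, recs, minMolNum = 4L, nMol = nMol)
  expect_identical(out$aid, c(1L, 4L, 5L))
})

test_that("minimum-table-size filter agrees with a direct predicate scan", {
  for (seed in c(3L, 9L)) {
    corp <- fixCorpus(seed = seed, nAssays = 40L)
    res <- rankedResults(corp)
    out <- filterMinMolecules(res, corp$records, minMolNum = 10L, nMol = 8L)
    keep <- vapply(res$aid, function(a) {
      tab <- outcomes(corp$records[[as.character(a)]])
      thr <- if (sum(tab$outcome == "Active") == 0) 16L else 10L
      nrow(tab) >= thr
    }, logical(1))
    expect_identical(out$aid, res$aid[keep])
  }
})

test_that("sequence-identity filter is strict at the threshold and replaces candidates", {
  corp <- fixCorpus()
  res <- rankedResults(corp)
  qseq <- corp$records[[1]]@target@sequence
  ## plant identities per unique target sequence: exactly at the threshold,
  ## just above it, the same protein, and a background far below
  seqs <- vapply(res$aid, function(a)
    corp$records[[as.character(a)]]@target@sequence, character(1))
  useqs <- unique(seqs)
  vals <- withr::with_seed(2, runif(length(useqs), 0, 0.25))
  vals[2] <- 0.30   # exactly the threshold: retained
  vals[3] <- 1.00   # same protein: removed
  vals[4] <- 0.31   # just above: removed
  prov <- mockIdentityProvider(
    data.frame(seqA = qseq, seqB = useqs, identity = vals))
  identOf <- vals[match(seqs, useqs)]
  q <- familyQuery(1, sequence = qseq)
  out <- filterSequenceIdentity(res, corp$records, q, 0.30, prov)
  expect_true(all(res$aid[identOf == 0.30] %in% out$aid))
  expect_false(any(res$aid[identOf > 0.30] %in% out$aid))
  expect_identical(out$aid, res$aid[identOf <= 0.30])
  ## replacement semantics: collection stops once maxAssayNum survive
  capped <- filterSequenceIdentity(res, corp$records, q, 0.30, prov,
                                   maxAssayNum = 4L)
  expect_identical(capped$aid, head(res$aid[identOf <= 0.30], 4L))
})

test_that("assessment parses verdicts, re-asks once, then defaults with a warning", {
  corp <- fixCorpus()
  rec <- corp$records[[1]]
  q <- familyQuery(1)
  good <- scriptedTextProvider("RELEVANT: yes\nCOUNTERSCREEN: no")
  a <- assessAssay(rec, q, good)
  expect_true(a@relevant); expect_false(a@counterscreen)
  ## first response malformed, second parsable: the re-ask recovers
  retry <- scriptedTextProvider(c("garbled", "RELEVANT: no\nCOUNTERSCREEN: yes"))
  a2 <- assessAssay(rec, q, retry)
  expect_false(a2@relevant); expect_true(a2@counterscreen)
  ## malformed twice: defaults plus warning
  bad <- scriptedTextProvider(c("garbled", "still garbled"))
  expect_warning(a3 <- assessAssay(rec, q, bad), regexp = "unparsable")
  expect_false(a3@relevant); expect_false(a3@counterscreen)
})

test_that("oracle-mock assessments equal the planted ground truth", {
  corp <- fixCorpus()
  q <- familyQuery(2)
  prov <- oracleTextProvider(corp$manifest, 2)
  for (a in corp$manifest$aid) {
    got <- assessAssay(corp$records[[as.character(a)]], q, prov)
    row <- corp$manifest[corp$manifest$aid == a, ]
    expect_identical(got@relevant, row$family == 2)
    expect_identical(got@counterscreen, row$counterscreen)
  }
})

test_that("selection keeps relevant assays in similarity order up to the cap", {
  mkAssess <- function(aidv, rel, cs = FALSE)
    new("AssayAssessment", aid = as.integer(aidv), relevant = rel,
        counterscreen = cs)
  res <- data.frame(aid = 1:12, similarity = seq(0.95, 0.40, length.out = 12))
  all12 <- lapply(1:12, mkAssess, rel = TRUE)
  out <- selectAssays(res, all12, maxAssayNum = 10L)
  expect_identical(out$aid, 1:10)
  none <- lapply(1:12, mkAssess, rel = FALSE)
  expect_identical(nrow(selectAssays(res, none, 10L)), 0L)
  mixed <- lapply(1:12, function(i) mkAssess(i, i %% 2 == 0, cs = i == 4))
  out2 <- selectAssays(res, mixed, maxAssayNum = 4L)
  expect_identical(out2$aid, c(2L, 4L, 6L, 8L))
  expect_identical(out2$counterscreen, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("relevance groups follow the published inequality chain exactly", {
  mk <- function(nRel, nTot) lapply(seq_len(nTot), function(i)
    new("AssayAssessment", aid = i, relevant = i <= nRel,
        counterscreen = FALSE))
  r <- relevanceRatio(mk(7, 10))
  expect_equal(r$x, 0.7)
  expect_identical(as.character(r$group), "High")
  r <- relevanceRatio(mk(1, 10))
  expect_equal(r$x, 0.1)
  expect_identical(as.character(r$group), "None")
  ## enumeration oracle over all counts
  expectedGroup <- function(x) {
    if (x >= 0.7) "High"
    else if (x > 0.4 && x < 0.7) "Medium"
    else if (x > 0.1 && x <= 0.4) "Low"
    else "None"
  }
  for (n in 0:10) {
    got <- relevanceRatio(mk(n, 10))
    expect_identical(as.character(got$group), expectedGroup(n / 10))
  }
  expect_error(relevanceRatio(list()), class = "amg_contract_error")
})

test_that("the cascade only shrinks the candidate set and matches the manifest oracle", {
  corp <- fixCorpus(seed = 5L, nAssays = 40L)
  emb <- hashEmbeddingProvider(64)
  idx <- buildAssayIndex(corp$records, emb)
  cfg <- retrievalConfig(k = 40L, minMolNum = 8L, maxAssayNum = 5L, seed = 2L)
  q <- familyQuery(1, uniprotId = corp$manifest$uniprot[1])
  ret <- retrieveAssays(q, idx, corp$records, cfg, emb,
                        oracleTextProvider(corp$manifest, 1))
  sizes <- vapply(ret$audit, length, integer(1))
  expect_true(all(diff(sizes) <= 0))
  ## oracle: rank exhaustively, apply predicates directly on the manifest
  ranked <- topK(idx, embedQuery(q, emb), k = 40L)
  man <- corp$manifest[match(ranked$aid, corp$manifest$aid), ]
  tabs <- lapply(ranked$aid, function(a) outcomes(corp$records[[as.character(a)]]))
  nAct <- vapply(tabs, function(t) sum(t$outcome == "Active"), integer(1))
  len <- vapply(tabs, nrow, integer(1))
  keep <- man$uniprot != q@uniprotId &
    len >= ifelse(nAct == 0, 16L, 8L) &
    man$family == 1
  expect_identical(ret$selected$aid, head(ranked$aid[keep], 5L))
  expect_identical(ret$selected$counterscreen,
                   man$counterscreen[keep][seq_len(nrow(ret$selected))])
})
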