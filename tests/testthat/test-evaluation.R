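test_that("diversity matches a double-loop oracle and its edge cases", {
  expect_equal(diversity(rep("CCO", 5)), 0.0)
  expect_error(diversity("CCO"), class = "amg_undefined_metric")
  smi <- withr::with_seed(3, sample(fixPool()$smiles, 10L))
  fp <- morganFingerprints(smi)
  ## brute-force pair loop
  ref <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    inter <- sum(fp[i, ] & fp[j, ])
    uni <- sum(fp[i, ] | fp[j, ])
    ref <- c(ref, 1 - inter / uni)
  }
  expect_equal(diversity(smi), mean(ref), tolerance = 1e-12)
  ## permutation invariance
  perm <- withr::with_seed(9, sample(smi))
  expect_equal(diversity(perm), diversity(smi), tolerance = 1e-12)
})

test_that("molecules with disjoint fingerprints have diversity one", {
  a <- "CCCCCC"        # aliphatic chain
  b <- "c1ccccc1"      # aromatic ring
  fp <- morganFingerprints(c(a, b))
  expect_identical(sum(fp[1, ] & fp[2, ]), 0L)  # construction check
  expect_equal(diversity(c(a, b)), 1.0)
})

test_that("high-affinity fraction uses a strict comparison", {
  expect_equal(highAffinityFraction(c(-9, -8.5), -8), 1.0)
  expect_equal(highAffinityFraction(c(-8, -7, -6), -7), 1 / 3)
  ## multi-reference targets compare against the best reference
  expect_equal(highAffinityFraction(c(-8, -7, -6), c(-7, -7.5)), 1 / 3)
  withr::with_seed(17, {
    for (i in 1:50) {
      g <- rnorm(20, -7); r <- rnorm(1, -7)
      expect_equal(highAffinityFraction(g, r), sum(g < r) / 20)
    }
  })
})

test_that("improvement equals the direct formula and is shift-invariant", {
  expect_equal(improvementOverBaseline(rep(-7, 5), c(-6, -8)), 0.0)
  expect_equal(improvementOverBaseline(rep(-8, 4), rep(-7, 10)), 1.0)
  withr::with_seed(23, {
    for (i in 1:50) {
      g <- rnorm(15, -7.5); b <- rnorm(40, -7)
      expect_equal(improvementOverBaseline(g, b),
                   mean(mean(b) - g), tolerance = 1e-12)
      shift <- rnorm(1, 0, 5)
      expect_equal(improvementOverBaseline(g + shift, b + shift),
                   improvementOverBaseline(g, b), tolerance = 1e-9)
    }
  })
  expect_equal(improvementOverBaseline(c(-8, -6), c(-9, -7, -5),
                                       baselineStat = "median"),
               0.0)
  expect_error(improvementOverBaseline(numeric(), -7),
               class = "amg_contract_error")
})

test_that("context similarity equals the brute-force similarity matrix", {
  gen <- withr::with_seed(5, sample(fixPool()$smiles, 5L))
  ctxm <- withr::with_seed(6, sample(fixPool()$smiles, 5L))
  got <- contextSimilarity(gen, ctxm)
  fpG <- morganFingerprints(gen); fpC <- morganFingerprints(ctxm)
  for (i in 1:5) {
    sims <- vapply(1:5, function(j) {
      inter <- sum(fpG[i, ] & fpC[j, ])
      inter / sum(fpG[i, ] | fpC[j, ])
    }, numeric(1))
    expect_equal(unname(got[i]), max(sims), tolerance = 1e-12)
  }
  ## a generated molecule identical to a context molecule scores 1
  expect_equal(unname(contextSimilarity(ctxm[1], ctxm)[1]), 1.0)
})

test_that("drug-likeness and accessibility scores live on the unit interval", {
  smi <- withr::with_seed(8, sample(fixPool()$smiles, 15L))
  props <- moleculeProperties(smi)
  expect_true(all(props$qed > 0 & props$qed < 1))
  expect_true(all(props$sa_norm >= 0 & props$sa_norm <= 1))
  expect_identical(props$size, heavyAtomCount(smi))
  ## sa_norm is the documented affine map of the raw score
  expect_equal(props$sa_norm, 1 - (props$sa_raw - 1) / 9, tolerance = 1e-12)
  ## repeated calls are deterministic (memoised backend)
  expect_identical(moleculeProperties(smi), props)
})

test_that("scoring skips invalid molecules and is reproducible", {
  sc <- hashDockingScorer(seed = 4L)
  smi <- head(fixPool()$smiles, 8L)
  s1 <- scoreWith(sc, smi, "targetA")
  expect_identical(s1, scoreWith(sc, smi, "targetA"))
  expect_true(all(s1 >= -10 & s1 <= -4))
  ## same molecules, different target: different scores
  expect_false(identical(s1, scoreWith(sc, smi, "targetB")))
  expect_warning(s2 <- scoreWith(sc, c(smi[1], "junk("), "targetA"),
                 regexp = "invalid")
  expect_identical(s2[1], s1[1])
  expect_true(is.na(s2[2]))
})

test_that("two-level aggregation matches an independent recomputation", {
  mkReport <- function(id, qed, sa, size) {
    structure(class = "amg_target_report", list(
      target = id,
      molecules = data.frame(qed = qed, sa_norm = sa, size = size),
      aggregates = list(qed_mean = mean(qed), qed_median = median(qed),
                        sa_norm_mean = mean(sa), sa_norm_median = median(sa),
                        size_mean = mean(size), size_median = median(size)),
      diversity = NA_real_, high_affinity = NA_real_,
      improvement = NA_real_, relevance_group = NA_character_))
  }
  ## two targets with per-target means 1 and 3 -> cross-target mean 2
  r1 <- mkReport("a", qed = c(1, 1), sa = c(0.5, 0.5), size = c(10, 10))
  r2 <- mkReport("b", qed = c(3, 3), sa = c(0.7, 0.7), size = c(20, 20))
  agg <- aggregateReports(list(r1, r2))
  expect_equal(agg$mean_of_means[agg$metric == "qed"], 2.0)
  ## random 5-target fixture vs flat independent two-level computation
  withr::with_seed(31, {
    reports <- lapply(1:5, function(i)
      mkReport(i, qed = runif(7), sa = runif(7), size = sample(10:30, 7)))
    agg2 <- aggregateReports(reports)
    perTargetMeans <- vapply(reports, function(r) mean(r$molecules$qed),
                             numeric(1))
    perTargetMedians <- vapply(reports, function(r) median(r$molecules$qed),
                               numeric(1))
    row <- agg2[agg2$metric == "qed", ]
    expect_equal(row$mean_of_means, mean(perTargetMeans), tolerance = 1e-12)
    expect_equal(row$median_of_means, median(perTargetMeans), tolerance = 1e-12)
    expect_equal(row$mean_of_medians, mean(perTargetMedians), tolerance = 1e-12)
    expect_equal(row$median_of_medians, median(perTargetMedians),
                 tolerance = 1e-12)
    ## equal molecule counts: mean-of-means equals the flat mean
    flat <- mean(unlist(lapply(reports, function(r) r$molecules$qed)))
    expect_equal(row$mean_of_means, flat, tolerance = 1e-12)
  })
})

test_that("a single-target single-molecule report reduces to that molecule", {
  smi <- fixPool()$smiles[1]
  rep1 <- evaluateTarget("t", smi)
  props <- moleculeProperties(smi)
  expect_equal(rep1$aggregates$qed_mean, props$qed)
  expect_equal(rep1$aggregates$size_mean, props$size)
  agg <- aggregateReports(list(rep1))
  expect_equal(agg$mean_of_means[agg$metric == "qed"], props$qed)
})

test_that("the planted scorer rewards similarity to the planted actives", {
  corp <- fixCorpus()
  sc <- plantedDockingScorer(corp$familyActives, seed = 2L)
  fam1 <- corp$familyActives[["1"]]
  inFam <- head(fam1, 10L)
  outFam <- head(setdiff(fixPool()$smiles, fam1), 10L)
  sIn <- scoreMolecules(sc, inFam, "1")
  sOut <- scoreMolecules(sc, outFam, "1")
  expect_lt(mean(sIn), mean(sOut))
  ## unknown target: no bonus anywhere
  sNone <- scoreMolecules(sc, inFam, "99")
  expect_gt(mean(sNone), mean(sIn))
})

test_that("alignment identity provider returns sensible fractions", {
  p <- alignmentIdentityProvider()
  expect_equal(sequenceIdentity(p, "MKTAYIAKQR", "MKTAYIAKQR"), 1.0)
  expect_lt(sequenceIdentity(p, "MKTAYIAKQR", "MKTAYIAKQW"), 1.0)
  expect_gte(sequenceIdentity(p, "MKTAYIAKQR", "WWPGHHEELV"), 0.0)
})
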