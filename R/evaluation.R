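## Metric suite: fingerprint diversity, high-affinity fraction, two-level
## aggregation, improvement over a background score distribution,
## context-similarity diagnostics, and pluggable molecule scorers.

#' Average pairwise Tanimoto diversity
#'
#' Diversity of a molecule set is the mean over all unordered pairs of
#' `1 - Tanimoto similarity` on circular fingerprints: 0 for identical
#' molecules, approaching 1 for structurally unrelated sets.
#'
#' @param smiles character vector of at least two valid SMILES.
#' @param nbits fingerprint width (see [morganFingerprints()]).
#' @return diversity in \[0, 1\].
#' @export
diversity <- function(smiles, nbits = 2048L) {
  if (length(smiles) < 2L)
    amgStop("amg_undefined_metric", "diversity needs at least 2 molecules")
  fp <- morganFingerprints(smiles, nbits)
  sim <- tanimotoSimilarity(fp, fp)
  n <- nrow(sim)
  mean(1 - sim[upper.tri(sim)])
}

#' Fraction of generated molecules beating the reference score
#'
#' Docking convention: lower is better; the comparison is strict (a
#' generated molecule exactly at the reference score does not count). For
#' targets with several reference molecules, pass their best (lowest) score.
#'
#' @param genScores numeric vector of generated-molecule scores.
#' @param refScore reference score (scalar; if a vector, its minimum is
#'   used).
#' @return fraction in \[0, 1\].
#' @export
highAffinityFraction <- function(genScores, refScore) {
  stopifnot(length(genScores) > 0)
  mean(genScores < min(refScore))
}

#' Mean improvement of generated scores over a background distribution
#'
#' For a protein-specific background (e.g. a set of approved drugs docked
#' against the same target), the improvement of a generated molecule is
#' `location(background) - score`; positive values mean better (lower)
#' docking scores than the background. The summary is the mean over
#' generated molecules; the background location functional is the mean by
#' default, with the median available. Shifting every score (generated and
#' background) by a constant leaves the improvement unchanged.
#'
#' @param genScores numeric vector of generated-molecule scores.
#' @param baselineScores non-empty numeric vector of background scores.
#' @param baselineStat `"mean"` or `"median"` of the background.
#' @return mean improvement (same units as the scores).
#' @export
improvementOverBaseline <- function(genScores, baselineScores,
                                    baselineStat = c("mean", "median")) {
  if (!length(genScores) || !length(baselineScores))
    amgStop("amg_contract_error", "scores and baseline must be non-empty")
  baselineStat <- match.arg(baselineStat)
  loc <- if (baselineStat == "mean") mean(baselineScores)
         else median(baselineScores)
  mean(loc - genScores)
}

#' Maximum similarity of each generated molecule to the context set
#'
#' Diagnoses whether generation copies its context: for each generated
#' molecule, the maximum Tanimoto similarity to any context molecule.
#'
#' @param generated,contextMolecules non-empty character vectors of SMILES.
#' @param nbits fingerprint width.
#' @return numeric vector, one maximum similarity per generated molecule.
#' @export
contextSimilarity <- function(generated, contextMolecules, nbits = 2048L) {
  if (!length(generated) || !length(contextMolecules))
    amgStop("amg_contract_error", "both molecule lists must be non-empty")
  sim <- tanimotoSimilarity(morganFingerprints(generated, nbits),
                            morganFingerprints(contextMolecules, nbits))
  apply(sim, 1L, max)
}

#' Score molecules with a pluggable scorer
#'
#' Runs the scorer over the valid molecules; invalid SMILES are skipped with
#' a warning and receive `NA` scores rather than aborting the run.
#'
#' @param scorer a [MoleculeScorer-class].
#' @param smiles character vector.
#' @param targetId target identifier passed through to the scorer.
#' @return numeric vector of scores aligned with `smiles` (`NA` where
#'   skipped).
#' @export
scoreWith <- function(scorer, smiles, targetId) {
  valid <- isValidSmiles(smiles)
  if (any(!valid))
    amgWarn("skipping %d invalid molecule(s) in scoring", sum(!valid))
  out <- rep(NA_real_, length(smiles))
  if (any(valid))
    out[valid] <- scoreMolecules(scorer, smiles[valid], targetId)
  out
}

#' Per-target evaluation report
#'
#' Computes the per-molecule metric table (drug-likeness, normalized
#' synthetic accessibility, heavy-atom size, optional docking score) and the
#' per-target aggregates: mean and median of each metric, diversity,
#' high-affinity fraction against a reference score, and improvement over a
#' background distribution.
#'
#' @param targetId identifier for the target.
#' @param smiles generated molecules (valid SMILES).
#' @param scorer optional [MoleculeScorer-class] for docking-style scores.
#' @param refScore optional reference score for the high-affinity fraction.
#' @param baselineScores optional background score vector for improvement.
#' @param relevanceGroup optional relevance-group label for this target.
#' @return list of class `amg_target_report`: `target`, `molecules`
#'   (per-molecule data.frame), `aggregates` (named list of mean/median per
#'   metric), `diversity`, `high_affinity`, `improvement`,
#'   `relevance_group`.
#' @export
evaluateTarget <- function(targetId, smiles, scorer = NULL, refScore = NULL,
                           baselineScores = NULL, relevanceGroup = NA) {
  stopifnot(length(smiles) > 0)
  props <- moleculeProperties(smiles)
  if (!is.null(scorer))
    props$dock_score <- scoreWith(scorer, smiles, targetId)
  agg <- list()
  for (m in intersect(c("qed", "sa_norm", "size", "dock_score"), names(props))) {
    agg[[paste0(m, "_mean")]] <- mean(props[[m]], na.rm = TRUE)
    agg[[paste0(m, "_median")]] <- median(props[[m]], na.rm = TRUE)
  }
  structure(class = "amg_target_report", list(
    target = targetId,
    molecules = props,
    aggregates = agg,
    diversity = if (length(smiles) >= 2) diversity(smiles) else NA_real_,
    high_affinity = if (!is.null(scorer) && !is.null(refScore))
      highAffinityFraction(props$dock_score[!is.na(props$dock_score)],
                           refScore) else NA_real_,
    improvement = if (!is.null(scorer) && !is.null(baselineScores))
      improvementOverBaseline(props$dock_score[!is.na(props$dock_score)],
                              baselineScores) else NA_real_,
    relevance_group = as.character(relevanceGroup)))
}

#' Two-level aggregation across targets
#'
#' Metrics are first averaged within each target, then summarized across
#' targets: the cross-target mean and median of the per-target means, and
#' likewise of the per-target medians. With equal molecule counts per target
#' the mean-of-means equals the flat mean.
#'
#' @param reports list of reports from [evaluateTarget()].
#' @return data.frame with one row per metric and columns `mean_of_means`,
#'   `median_of_means`, `mean_of_medians`, `median_of_medians`.
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1)
  metrics <- unique(unlist(lapply(reports, function(r)
    sub("_(mean|median)$", "", names(r$aggregates)))))
  rows <- lapply(metrics, function(m) {
    means <- vapply(reports, function(r)
      r$aggregates[[paste0(m, "_mean")]] %||% NA_real_, numeric(1))
    medians <- vapply(reports, function(r)
      r$aggregates[[paste0(m, "_median")]] %||% NA_real_, numeric(1))
    data.frame(metric = m,
               mean_of_means = mean(means, na.rm = TRUE),
               median_of_means = median(means, na.rm = TRUE),
               mean_of_medians = mean(medians, na.rm = TRUE),
               median_of_medians = median(medians, na.rm = TRUE))
  })
  extra <- lapply(c("diversity", "improvement", "high_affinity"), function(m) {
    vals <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1))
    data.frame(metric = m, mean_of_means = mean(vals, na.rm = TRUE),
               median_of_means = median(vals, na.rm = TRUE),
               mean_of_medians = NA_real_, median_of_medians = NA_real_)
  })
  out <- do.call(rbind, c(rows, extra))
  rownames(out) <- NULL
  out
}

## ---- scorers ---------------------------------------------------------------

#' Deterministic hash-based mock docking scorer
#'
#' Scores are a seeded pure function of the canonical SMILES and the target
#' identifier, mapped into a docking-like range (about -10 to -4 kcal/mol).
#' Useful wherever a reproducible stand-in for an external docking engine is
#' needed.
#'
#' @slot seed integer salt.
#' @exportClass HashDockingScorer
setClass("HashDockingScorer", contains = "MoleculeScorer",
         representation(seed = "integer"))

#' @param seed integer salt.
#' @return a `HashDockingScorer`.
#' @rdname HashDockingScorer-class
#' @export
hashDockingScorer <- function(seed = 1L) {
  new("HashDockingScorer", seed = as.integer(seed),
      tag = sprintf("hash-dock-%d", seed))
}

#' @describeIn HashDockingScorer-class deterministic scoring
#' @param scorer scorer object.
#' @param smiles molecules to score.
#' @param targetId target identifier.
#' @export
setMethod("scoreMolecules", "HashDockingScorer",
          function(scorer, smiles, targetId) {
  can <- canonicalizeSmiles(smiles)
  vapply(can, function(s)
    -4 - 6 * hashUnit(paste(scorer@seed, targetId, s, sep = "|")),
    numeric(1), USE.NAMES = FALSE)
})

#' Planted-effect mock docking scorer
#'
#' A synthetic scorer with known structure: molecules structurally similar
#' to a planted set of target-specific actives receive better (lower)
#' scores. The score is `base - bonus * maxsim + noise`, where `maxsim` is
#' the molecule's maximum Tanimoto similarity to the planted actives of the
#' scored target and the noise term is a deterministic hash-derived normal
#' deviate. Pipelines fed relevant context should therefore recover positive
#' improvement over background molecules, and irrelevant-context pipelines
#' should not.
#'
#' @slot familyActives named list: target id -> character vector of planted
#'   active SMILES.
#' @slot base base score (kcal/mol-like).
#' @slot bonus score bonus at similarity 1.
#' @slot noiseSd standard deviation of the hash-derived noise.
#' @slot seed integer salt.
#' @exportClass PlantedDockingScorer
setClass("PlantedDockingScorer", contains = "MoleculeScorer",
         representation(familyActives = "list", base = "numeric",
                        bonus = "numeric", noiseSd = "numeric",
                        seed = "integer"))

#' @param familyActives named list mapping target ids to planted active
#'   SMILES.
#' @param base,bonus,noiseSd score model parameters.
#' @param seed integer salt.
#' @return a `PlantedDockingScorer`.
#' @rdname PlantedDockingScorer-class
#' @export
plantedDockingScorer <- function(familyActives, base = -5, bonus = 3,
                                 noiseSd = 0.3, seed = 1L) {
  new("PlantedDockingScorer", familyActives = familyActives, base = base,
      bonus = bonus, noiseSd = noiseSd, seed = as.integer(seed),
      tag = sprintf("planted-dock-%d", seed))
}

#' @describeIn PlantedDockingScorer-class scaffold-aware scoring
#' @param scorer scorer object.
#' @param smiles molecules to score.
#' @param targetId target identifier (must name an entry of
#'   `familyActives`; unknown targets get no bonus).
#' @export
setMethod("scoreMolecules", "PlantedDockingScorer",
          function(scorer, smiles, targetId) {
  can <- canonicalizeSmiles(smiles)
  actives <- scorer@familyActives[[as.character(targetId)]]
  maxsim <- if (is.null(actives) || !length(actives)) rep(0, length(can))
            else contextSimilarity(can, actives)
  noise <- vapply(can, function(s)
    qnorm(hashUnit(paste(scorer@seed, targetId, s, "noise", sep = "|"))),
    numeric(1), USE.NAMES = FALSE)
  scorer@base - scorer@bonus * maxsim + scorer@noiseSd * noise
})

## ---- identity providers ----------------------------------------------------

#' Table-backed mock sequence-identity provider
#'
#' Returns planted identity values from a lookup keyed on the two sequences
#' (order-insensitive); pairs not in the table fall back to `default`.
#'
#' @slot table named numeric vector keyed by `paste(sort(c(a, b)), collapse = "|")`.
#' @slot default identity returned for unknown pairs.
#' @exportClass MockIdentityProvider
setClass("MockIdentityProvider", contains = "SequenceIdentityProvider",
         representation(table = "numeric", default = "numeric"))

#' @param pairs data.frame with columns `seqA`, `seqB`, `identity`.
#' @param default identity for pairs not listed.
#' @return a `MockIdentityProvider`.
#' @rdname MockIdentityProvider-class
#' @export
mockIdentityProvider <- function(pairs, default = 0) {
  key <- vapply(seq_len(nrow(pairs)), function(i)
    paste(sort(c(pairs$seqA[i], pairs$seqB[i])), collapse = "|"), character(1))
  new("MockIdentityProvider", table = setNames(pairs$identity, key),
      default = default)
}

#' @describeIn MockIdentityProvider-class planted lookup
#' @param provider provider object.
#' @param seqA,seqB sequences.
#' @export
setMethod("sequenceIdentity", "MockIdentityProvider",
          function(provider, seqA, seqB) {
  key <- paste(sort(c(seqA, seqB)), collapse = "|")
  if (key %in% names(provider@table)) unname(provider@table[[key]])
  else provider@default
})

#' Alignment-based sequence-identity provider
#'
#' Computes percent identity from a global pairwise alignment
#' (Biostrings), divided by 100 to a fraction.
#'
#' @exportClass AlignmentIdentityProvider
setClass("AlignmentIdentityProvider", contains = "SequenceIdentityProvider")

#' @return an `AlignmentIdentityProvider`.
#' @rdname AlignmentIdentityProvider-class
#' @export
alignmentIdentityProvider <- function() new("AlignmentIdentityProvider")

#' @describeIn AlignmentIdentityProvider-class global-alignment identity
#' @param provider provider object.
#' @param seqA,seqB amino-acid sequences.
#' @export
setMethod("sequenceIdentity", "AlignmentIdentityProvider",
          function(provider, seqA, seqB) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(seqA),
                                       Biostrings::AAString(seqB))
  Biostrings::pid(aln) / 100
})
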