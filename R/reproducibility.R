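#' Normalised overlap (Jaccard index) of two gene sets
#'
#' \code{|A intersect B| / |A union B|}; the reproducibility statistic for
#' driver-networks inferred from independent cohorts. Defined as 0 when
#' both sets are empty.
#'
#' @param a,b character vectors of gene symbols (or [DriverNetwork-class]
#'   objects, whose member genes are used).
#' @return numeric in [0, 1].
#' @examples
#' normalizedOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 0.5
#' @export
normalizedOverlap <- function(a, b) {
  if (is(a, "DriverNetwork")) a <- memberGenes(a)
  if (is(b, "DriverNetwork")) b <- memberGenes(b)
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Add-one empirical p-value
#'
#' \code{(1 + #\{null_i >= observed\}) / (1 + reps)}: the pseudo-count
#' estimator, never exactly 0 at finite reps. The raw exceedance count is
#' attached as attribute \code{"exceedances"}.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @return p-value in (0, 1].
#' @examples
#' empiricalPValue(0.9, rep(0.1, 999))  # 0.001
#' @export
empiricalPValue <- function(observed, null) {
  stopifnot(length(null) >= 1L)
  k <- sum(null >= observed)
  p <- (1 + k) / (1 + length(null))
  attr(p, "exceedances") <- k
  p
}

#' Expression-randomisation null for cross-cohort overlap
#'
#' Keeps the true seed genes but shuffles the probe identity labels of each
#' cohort's expression matrix (rows keep their values; labels are
#' reassigned, independently per cohort per rep), re-runs the expansion
#' from the same seeds in both cohorts and records the normalised overlap
#' of the two resulting member sets. This preserves the numbers of
#' differentially expressed probes while destroying their identity and
#' network placement. Each rep uses the single-run (non-resampled)
#' expansion; set \code{reps} accordingly.
#'
#' @param cohortA,cohortB two [OmicsCohort-class] objects.
#' @param net the shared [NetworkSpace-class].
#' @param seeds a [SeedSet-class] (or gene vector) used in both cohorts.
#' @param subtype the subtype; defaults to the seed set's subtype.
#' @param reps number of permutation reps (default 1000).
#' @param rngSeed integer seed.
#' @param observed observed overlap; computed from the unpermuted
#'   expansions when NULL.
#' @param topFracP,topFracMedian,deltaTopFrac selection fractions, see
#'   [differentialExpression()] and [coexpressionThreshold()].
#' @return a [NullDistribution-class] with scheme
#'   \code{"expression_randomisation"}.
#' @export
expressionRandomizationNull <- function(cohortA, cohortB, net, seeds,
                                        subtype = NULL, reps = 1000L,
                                        rngSeed = 1L, observed = NULL,
                                        topFracP = 0.02,
                                        topFracMedian = 0.01,
                                        deltaTopFrac = 0.002) {
  seedsVec <- if (is(seeds, "SeedSet")) seedGenes(seeds) else toupper(seeds)
  if (is.null(subtype))
    subtype <- if (is(seeds, "SeedSet")) subtypeOf(seeds) else
      stop("subtype must be given when seeds is a plain gene vector")
  ctxA <- .expansionContext(net, cohortA, subtype)
  ctxB <- .expansionContext(net, cohortB, subtype)
  if (is.null(observed)) {
    mA <- .memberGenes(ctxA, .runExpansion(
      ctxA, seedsVec, topFracP = topFracP, topFracMedian = topFracMedian,
      deltaTopFrac = deltaTopFrac))
    mB <- .memberGenes(ctxB, .runExpansion(
      ctxB, seedsVec, topFracP = topFracP, topFracMedian = topFracMedian,
      deltaTopFrac = deltaTopFrac))
    observed <- normalizedOverlap(mA, mB)
  }
  # per-row statistics and standardised matrices are invariant under the
  # label permutation; each rep only re-indexes them
  pctxA <- .permutationContext(ctxA, topFracP, topFracMedian)
  pctxB <- .permutationContext(ctxB, topFracP, topFracMedian)
  set.seed(rngSeed)
  overlaps <- vapply(seq_len(reps), function(r) {
    permA <- sample.int(nrow(ctxA$X))
    permB <- sample.int(nrow(ctxB$X))
    mA <- .runPermuted(ctxA, pctxA, permA, seedsVec, deltaTopFrac)
    mB <- .runPermuted(ctxB, pctxB, permB, seedsVec, deltaTopFrac)
    normalizedOverlap(mA, mB)
  }, numeric(1L))
  new("NullDistribution", scheme = "expression_randomisation",
      overlaps = overlaps, observed = observed,
      pValue = as.numeric(empiricalPValue(observed, overlaps)),
      reps = as.integer(reps))
}

#' Seed-randomisation null for cross-cohort overlap
#'
#' Per rep, draws a random seed set of the same size as the observed one
#' from the shared seed universe (genes present in the network with both
#' copy-number and expression data in both cohorts), expands it with the
#' original expression data in BOTH cohorts — the two cohorts always
#' receive the identical random seed list — and records the normalised
#' overlap.
#'
#' @inheritParams expressionRandomizationNull
#' @param nSeeds number of random seeds per rep (use the observed seed
#'   count).
#' @param subtype subtype name.
#' @param returnSeeds also record the drawn seed lists (run manifest).
#' @return a [NullDistribution-class] with scheme
#'   \code{"seed_randomisation"}; when \code{returnSeeds}, the drawn lists
#'   are attached as attribute \code{"seedLists"}.
#' @export
seedRandomizationNull <- function(cohortA, cohortB, net, nSeeds, subtype,
                                  reps = 1000L, rngSeed = 1L,
                                  observed = NA_real_,
                                  returnSeeds = FALSE,
                                  topFracP = 0.02, topFracMedian = 0.01,
                                  deltaTopFrac = 0.002) {
  stopifnot(nSeeds >= 1L)
  ctxA <- .expansionContext(net, cohortA, subtype)
  ctxB <- .expansionContext(net, cohortB, subtype)
  universe <- intersect(ctxA$genes, ctxB$genes)
  universe <- universe[universe %in% rownames(cohortA@cna) &
                       universe %in% rownames(cohortB@cna)]
  if (length(universe) < nSeeds)
    stop("seed universe (", length(universe),
         " genes) smaller than nSeeds = ", nSeeds)
  # expression is not randomised: the DE selection and edge qualification
  # are identical across reps, only the seed set changes
  runA <- .runExpansion(ctxA, character(0), topFracP = topFracP,
                        topFracMedian = topFracMedian,
                        deltaTopFrac = deltaTopFrac, keepStats = TRUE)
  runB <- .runExpansion(ctxB, character(0), topFracP = topFracP,
                        topFracMedian = topFracMedian,
                        deltaTopFrac = deltaTopFrac, keepStats = TRUE)
  set.seed(rngSeed)
  seedLists <- vector("list", reps)
  overlaps <- vapply(seq_len(reps), function(r) {
    s <- sample(universe, nSeeds)
    seedLists[[r]] <<- s
    mA <- ctxA$genes[.bfs(ctxA, unname(ctxA$gidx[s]), runA$deGene,
                          runA$qual)$member]
    mB <- ctxB$genes[.bfs(ctxB, unname(ctxB$gidx[s]), runB$deGene,
                          runB$qual)$member]
    normalizedOverlap(mA, mB)
  }, numeric(1L))
  nd <- new("NullDistribution", scheme = "seed_randomisation",
            overlaps = overlaps, observed = observed,
            pValue = if (is.na(observed)) NA_real_ else
              as.numeric(empiricalPValue(observed, overlaps)),
            reps = as.integer(reps))
  if (returnSeeds) attr(nd, "seedLists") <- seedLists
  nd
}

#' Overlap of resampling-stable differentially expressed genes
#'
#' The control comparison: normalised overlap of the two cohorts' gene sets
#' selected by differential expression in at least \code{membershipMin} of
#' the resampling reps (see [resampledDEGenes()]).
#'
#' @param freqA,freqB named numeric vectors of per-gene selection
#'   frequencies from two cohorts.
#' @param membershipMin frequency cutoff (default 0.5).
#' @return numeric overlap in [0, 1].
#' @export
overlapOfDEGenes <- function(freqA, freqB, membershipMin = 0.5) {
  normalizedOverlap(names(freqA)[freqA >= membershipMin],
                    names(freqB)[freqB >= membershipMin])
}

#' Cross-cohort reproducibility report
#'
#' Expands the given seeds in both cohorts (single-run), computes the
#' observed normalised overlap and both randomisation nulls, and returns a
#' summary table (observed overlap, null mean and sd, empirical p per
#' scheme).
#'
#' @inheritParams expressionRandomizationNull
#' @param repsSeedNull,repsExprNull reps per scheme.
#' @return list with elements \code{observed} (numeric),
#'   \code{seedNull} and \code{exprNull} ([NullDistribution-class]) and
#'   \code{table} (data.frame in the layout observed / seed-randomisation /
#'   expression-randomisation).
#' @export
reproducibilityReport <- function(cohortA, cohortB, net, seeds,
                                  subtype = NULL,
                                  repsSeedNull = 1000L,
                                  repsExprNull = 1000L, rngSeed = 1L,
                                  topFracP = 0.02, topFracMedian = 0.01,
                                  deltaTopFrac = 0.002) {
  seedsVec <- if (is(seeds, "SeedSet")) seedGenes(seeds) else toupper(seeds)
  if (is.null(subtype))
    subtype <- if (is(seeds, "SeedSet")) subtypeOf(seeds) else
      stop("subtype must be given when seeds is a plain gene vector")
  ctxA <- .expansionContext(net, cohortA, subtype)
  ctxB <- .expansionContext(net, cohortB, subtype)
  mA <- .memberGenes(ctxA, .runExpansion(
    ctxA, seedsVec, topFracP = topFracP, topFracMedian = topFracMedian,
    deltaTopFrac = deltaTopFrac))
  mB <- .memberGenes(ctxB, .runExpansion(
    ctxB, seedsVec, topFracP = topFracP, topFracMedian = topFracMedian,
    deltaTopFrac = deltaTopFrac))
  observed <- normalizedOverlap(mA, mB)
  sn <- seedRandomizationNull(cohortA, cohortB, net,
                              nSeeds = length(seedsVec), subtype = subtype,
                              reps = repsSeedNull, rngSeed = rngSeed,
                              observed = observed, topFracP = topFracP,
                              topFracMedian = topFracMedian,
                              deltaTopFrac = deltaTopFrac)
  en <- expressionRandomizationNull(cohortA, cohortB, net, seedsVec,
                                    subtype = subtype, reps = repsExprNull,
                                    rngSeed = rngSeed + 1L,
                                    observed = observed,
                                    topFracP = topFracP,
                                    topFracMedian = topFracMedian,
                                    deltaTopFrac = deltaTopFrac)
  tab <- data.frame(
    quantity = c("normalised overlap of driver-networks",
                 "normalised overlap from seed randomisation",
                 "normalised overlap from expression randomisation"),
    value = c(observed, mean(sn@overlaps), mean(en@overlaps)),
    sd = c(NA, stats::sd(sn@overlaps), stats::sd(en@overlaps)),
    p_value = c(NA, sn@pValue, en@pValue))
  list(observed = observed, seedNull = sn, exprNull = en, table = tab)
}
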