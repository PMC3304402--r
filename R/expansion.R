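#' Expand a driver-network from seed genes (single run)
#'
#' Grows the subtype driver-network to its fixed point. Starting from the
#' seeds, every direct network neighbour \code{v} of a current member
#' \code{m} is included when (a) \code{v} is differentially overexpressed,
#' or (b) \code{m} is differentially expressed (seeds only count if they
#' pass the differential-expression filter themselves) and the edge
#' \code{m--v} has differential co-expression at or above the global
#' threshold (the top \code{deltaTopFrac} of all network edge deltas). The
#' process repeats for every newly added gene until no inclusion occurs;
#' the result does not depend on the processing order. Seeds absent from
#' the network space are retained as isolated members with a warning.
#'
#' @param seeds a [SeedSet-class] or character vector of seed gene symbols.
#' @param net a [NetworkSpace-class].
#' @param cohort an [OmicsCohort-class].
#' @param subtype the subtype; defaults to the seed set's subtype.
#' @param de optional precomputed [DifferentialExpressionResult-class] for
#'   the same subtype; computed from the cohort when missing.
#' @param deltaThreshold optional fixed co-expression cutoff; computed from
#'   the global edge delta distribution when missing.
#' @param topFracP,topFracMedian,deltaTopFrac selection fractions, see
#'   [differentialExpression()] and [coexpressionThreshold()].
#' @param respectDirection traverse directed edges downstream only
#'   (default FALSE: arrows are annotation, not traversal constraints).
#' @param ... further arguments passed to the differential-expression step
#'   (\code{variant}, \code{strictBonferroni}, \code{bonferroniAlpha}).
#' @return a [DriverNetwork-class] with membership frequencies of 1.
#' @export
expandDriverNetwork <- function(seeds, net, cohort, subtype = NULL,
                                de = NULL, deltaThreshold = NULL,
                                topFracP = 0.02, topFracMedian = 0.01,
                                deltaTopFrac = 0.002,
                                respectDirection = FALSE, ...) {
  seedGenesVec <- if (is(seeds, "SeedSet")) seedGenes(seeds) else toupper(seeds)
  if (is.null(subtype))
    subtype <- if (is(seeds, "SeedSet")) subtypeOf(seeds) else
      stop("subtype must be given when seeds is a plain gene vector")
  if (!length(seedGenesVec)) stop("seeds must be non-empty")
  if (!is.null(de) && subtypeOf(de) != subtype)
    stop("de was computed for subtype ", subtypeOf(de), ", not ", subtype)
  ctx <- .expansionContext(net, cohort, subtype, respectDirection)
  run <- .runExpansion(ctx, seedGenesVec,
                       topFracP = topFracP, topFracMedian = topFracMedian,
                       deltaTopFrac = deltaTopFrac,
                       fixedDeltaThreshold = deltaThreshold,
                       keepStats = TRUE, ...)
  if (!is.null(de)) {
    # honour a caller-supplied DE selection instead of the recomputed one
    deGene <- ctx$genes %in% de@selectedGenes
    run <- .rerunWithDE(ctx, seedGenesVec, deGene,
                        if (is.null(deltaThreshold)) run$deltaThreshold
                        else deltaThreshold,
                        run)
  }
  if (length(run$extraSeeds))
    warning("seed gene(s) not in the network space, kept as isolated ",
            "members: ", paste(run$extraSeeds, collapse = ", "))
  .assembleDriverNetwork(ctx, run, net, subtype)
}

# re-run only the fixed-point part with an externally supplied DE gene set
.rerunWithDE <- function(ctx, seeds, deGene, thr, statsRun) {
  qual <- statsRun$delta >= thr
  seeds <- toupper(seeds)
  seedIdx <- unname(ctx$gidx[seeds[seeds %in% ctx$genes]])
  bfs <- .bfs(ctx, seedIdx, deGene, qual)
  out <- statsRun
  out$member <- bfs$member; out$reason <- bfs$reason; out$deGene <- deGene
  out$deltaThreshold <- thr; out$qual <- qual
  out$extraSeeds <- setdiff(seeds, ctx$genes)
  out
}

.reasonLabels <- c("seed", "seed+differential_expression",
                   "differential_expression", "coexpression_only")

.assembleDriverNetwork <- function(ctx, run, net, subtype,
                                   frequencies = NULL) {
  genes <- c(ctx$genes[run$member], run$extraSeeds)
  reason <- c(.reasonLabels[run$reason[run$member]],
              rep("seed", length(run$extraSeeds)))
  isSeed <- reason %in% c("seed", "seed+differential_expression")
  freq <- if (is.null(frequencies)) rep(1, length(genes))
          else unname(frequencies[genes])
  members <- data.frame(gene = genes, is_seed = isSeed,
                        inclusion_reason = reason,
                        membership_frequency = freq,
                        stringsAsFactors = FALSE)
  members <- members[order(-members$is_seed, members$gene), , drop = FALSE]
  rownames(members) <- NULL
  # induced interactome edges, annotated with the run's correlations
  ed <- networkEdges(net)
  keep <- ed$source %in% genes & ed$target %in% genes
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed)) {
    a <- unname(ctx$gidx[ed$source]); b <- unname(ctx$gidx[ed$target])
    key <- as.numeric(pmin(a, b)) * (ctx$nG + 1) + pmax(a, b)
    ekey <- as.numeric(ctx$eu) * (ctx$nG + 1) + ctx$ev
    idx <- match(key, ekey)
    ed$r_in <- run$rIn[idx]; ed$r_out <- run$rOut[idx]
    ed$delta <- run$delta[idx]
  } else {
    ed$r_in <- ed$r_out <- ed$delta <- numeric(0)
  }
  rownames(ed) <- NULL
  new("DriverNetwork", subtype = subtype, members = members, edges = ed,
      deltaThreshold = unname(run$deltaThreshold))
}

#' Resampling-stabilised driver-network
#'
#' Guards the expansion against outlier samples: \code{reps} times, a
#' stratified random subset of \code{sampleFrac} of the samples is drawn
#' (without replacement, preserving subtype proportions), the
#' differential-expression selection and the global co-expression threshold
#' are recomputed on the subsample, and the network is expanded from the
#' same seeds. Genes appearing in at least \code{membershipMin} of the
#' resampled networks form the final driver-network; seeds are retained
#' regardless (they are data-anchored, not expansion-derived) unless
#' \code{strictSeedFilter = TRUE}. Membership frequencies are reported for
#' every gene that ever entered a resampled network.
#'
#' @inheritParams expandDriverNetwork
#' @param sampleFrac fraction of samples drawn per rep (default 0.8).
#' @param reps number of resampling repetitions (default 1000).
#' @param membershipMin minimum membership frequency (default 0.5).
#' @param rngSeed integer seed controlling the whole resampling schedule.
#' @param strictSeedFilter apply the frequency filter to seeds too.
#' @param recomputeThreshold recompute the co-expression threshold per
#'   subsample (default) or reuse the full-cohort threshold.
#' @param mainComponentOnly drop satellite subnetworks, keeping only the
#'   largest connected component (default FALSE: satellites are retained).
#' @return a [DriverNetwork-class]; inclusion reasons come from the
#'   full-cohort run (genes never included there are labelled by their most
#'   frequent reason across reps), and the attribute \code{"frequencies"}
#'   carries the frequency of every ever-included gene.
#' @export
resampledDriverNetwork <- function(seeds, net, cohort, subtype = NULL,
                                   sampleFrac = 0.8, reps = 1000L,
                                   membershipMin = 0.5, rngSeed = 1L,
                                   strictSeedFilter = FALSE,
                                   recomputeThreshold = TRUE,
                                   mainComponentOnly = FALSE,
                                   topFracP = 0.02, topFracMedian = 0.01,
                                   deltaTopFrac = 0.002,
                                   respectDirection = FALSE, ...) {
  seedGenesVec <- if (is(seeds, "SeedSet")) seedGenes(seeds) else toupper(seeds)
  if (is.null(subtype))
    subtype <- if (is(seeds, "SeedSet")) subtypeOf(seeds) else
      stop("subtype must be given when seeds is a plain gene vector")
  stopifnot(reps >= 1L, sampleFrac > 0, sampleFrac <= 1)
  ctx <- .expansionContext(net, cohort, subtype, respectDirection)
  full <- .runExpansion(ctx, seedGenesVec,
                        topFracP = topFracP, topFracMedian = topFracMedian,
                        deltaTopFrac = deltaTopFrac, keepStats = TRUE, ...)
  nIn <- sum(ctx$inMask)
  if (floor(sampleFrac * nIn) < 2L)
    stop("subsampling leaves < 2 subtype samples; increase sampleFrac ",
         "or provide more data")
  set.seed(rngSeed)
  repSeeds <- sample.int(.Machine$integer.max, reps)
  counts <- numeric(ctx$nG)
  reasonCounts <- matrix(0L, ctx$nG, 4L)
  for (r in seq_len(reps)) {
    set.seed(repSeeds[r])
    idx <- .stratifiedSample(ctx$labels, sampleFrac)
    run <- .runExpansion(ctx, seedGenesVec, sampleIdx = idx,
                         topFracP = topFracP,
                         topFracMedian = topFracMedian,
                         deltaTopFrac = deltaTopFrac,
                         fixedDeltaThreshold =
                           if (recomputeThreshold) NULL
                           else full$deltaThreshold, ...)
    counts <- counts + run$member
    inc <- which(run$member)
    reasonCounts[cbind(inc, run$reason[inc])] <-
      reasonCounts[cbind(inc, run$reason[inc])] + 1L
  }
  freq <- counts / reps
  seedIdx <- unname(ctx$gidx[seedGenesVec[seedGenesVec %in% ctx$genes]])
  keep <- freq >= membershipMin
  if (!strictSeedFilter) keep[seedIdx] <- TRUE
  # reasons: full-cohort run where available, else majority across reps
  reason <- full$reason
  missing <- which(keep & reason == 0L)
  if (length(missing))
    reason[missing] <- max.col(reasonCounts[missing, , drop = FALSE],
                               ties.method = "first")
  res <- full
  res$member <- keep
  res$reason <- reason
  everIn <- freq > 0 | seq_len(ctx$nG) %in% seedIdx
  frequencies <- stats::setNames(freq[everIn], ctx$genes[everIn])
  if (length(full$extraSeeds))
    frequencies[full$extraSeeds] <- 1
  memberFreq <- stats::setNames(freq, ctx$genes)
  memberFreq[full$extraSeeds] <- 1
  dn <- .assembleDriverNetwork(ctx, res, net, subtype,
                               frequencies = memberFreq)
  if (mainComponentOnly && nrow(dn@members)) {
    comp <- networkComponents(net, dn@members$gene)
    keepG <- names(comp)[comp == 1L]
    dn@members <- dn@members[dn@members$gene %in% keepG, , drop = FALSE]
    dn@edges <- dn@edges[dn@edges$source %in% keepG &
                         dn@edges$target %in% keepG, , drop = FALSE]
  }
  attr(dn, "frequencies") <- frequencies
  dn
}

#' Resampled differential-expression gene frequencies
#'
#' The control comparison for driver-network reproducibility: how often each
#' gene is selected by the differential-expression criterion alone across
#' the same stratified resampling scheme.
#'
#' @inheritParams resampledDriverNetwork
#' @param cohort an [OmicsCohort-class].
#' @param subtype the subtype of interest.
#' @return named numeric vector: per-gene selection frequency across reps.
#' @export
resampledDEGenes <- function(cohort, subtype, sampleFrac = 0.8,
                             reps = 1000L, rngSeed = 1L,
                             topFracP = 0.02, topFracMedian = 0.01) {
  stopifnot(is(cohort, "OmicsCohort"), reps >= 1L)
  use <- analysedSamples(cohort)
  labels <- as.character(cohort@labels[use])
  X <- cohort@expression[, use, drop = FALSE]
  probes <- rownames(X)
  gene <- rep(NA_character_, length(probes))
  hit <- probes %in% names(cohort@probeMap)
  gene[hit] <- unname(cohort@probeMap[probes[hit]])
  allGenes <- sort(unique(gene[hit]))
  counts <- stats::setNames(numeric(length(allGenes)), allGenes)
  set.seed(rngSeed)
  repSeeds <- sample.int(.Machine$integer.max, reps)
  for (r in seq_len(reps)) {
    set.seed(repSeeds[r])
    idx <- .stratifiedSample(labels, sampleFrac)
    grp <- labels[idx] == subtype
    X1 <- X[, idx[grp], drop = FALSE]; X2 <- X[, idx[!grp], drop = FALSE]
    tt <- .welchT(X1, X2)
    md <- matrixStats::rowMedians(X1) - matrixStats::rowMedians(X2)
    sel <- .deSelect(tt$p, md, topFracP, topFracMedian)$selected
    g <- unique(gene[sel & !is.na(gene)])
    counts[g] <- counts[g] + 1
  }
  counts / reps
}

#' Write a driver-network as node and edge tables
#'
#' Writes \code{<prefix>_nodes.tsv} (gene, subtype, inclusion_reason,
#' membership_frequency, is_seed), \code{<prefix>_edges.tsv} (source,
#' target, provenance, directed, r_in, r_out, delta) and
#' \code{<prefix>_manifest.tsv} (realised thresholds), suitable for import
#' into graph-visualisation tools.
#'
#' @param dn a [DriverNetwork-class].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
writeDriverNetwork <- function(dn, prefix) {
  stopifnot(is(dn, "DriverNetwork"))
  nodes <- dn@members
  nodes$subtype <- dn@subtype
  nodes <- nodes[, c("gene", "subtype", "inclusion_reason",
                     "membership_frequency", "is_seed")]
  npath <- paste0(prefix, "_nodes.tsv")
  epath <- paste0(prefix, "_edges.tsv")
  mpath <- paste0(prefix, "_manifest.tsv")
  utils::write.table(nodes, npath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dn@edges[, c("source", "target", "provenance",
                                  "directed", "r_in", "r_out", "delta")],
                     epath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(key = "delta_threshold",
                                value = dn@deltaThreshold),
                     mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(npath, epath, mpath))
}
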