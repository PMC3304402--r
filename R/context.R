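# Internal expansion machinery.
#
# .expansionContext precomputes, once per (network, cohort, subtype), every
# index needed to re-run the full expansion cheaply on sample subsets
# (resampling) or row-permuted expression (expression randomisation):
# probe->gene indices, the unique gene-pair edge list, per-edge candidate
# probe pairs, and direction-agnostic adjacency. .runExpansion then performs
# one complete run: probe-level differential expression, edge differential
# correlations with the probe-pair rule, the global top-fraction delta
# threshold, and the frontier fixed-point expansion from the seeds.

.expansionContext <- function(net, cohort, subtype,
                              respectDirection = FALSE) {
  stopifnot(is(net, "NetworkSpace"), is(cohort, "OmicsCohort"))
  samples <- analysedSamples(cohort)
  labels <- as.character(cohort@labels[samples])
  if (!subtype %in% labels)
    stop("subtype ", subtype, " has no analysed samples")
  X <- cohort@expression[, samples, drop = FALSE]
  probes <- rownames(X)
  geneOfProbe <- rep(NA_character_, length(probes))
  hit <- probes %in% names(cohort@probeMap)
  geneOfProbe[hit] <- unname(cohort@probeMap[probes[hit]])
  genes <- intersect(networkNodes(net), unique(geneOfProbe[hit]))
  nG <- length(genes)
  gidx <- stats::setNames(seq_len(nG), genes)
  probeGene <- unname(gidx[geneOfProbe])            # NA when not a ctx gene

  # unique unordered gene pairs among ctx genes
  ed <- networkEdges(net)
  a <- unname(gidx[ed$source]); b <- unname(gidx[ed$target])
  ok <- !is.na(a) & !is.na(b)
  dirAB <- ed$directed[ok]
  u <- pmin(a[ok], b[ok]); v <- pmax(a[ok], b[ok])
  key <- as.numeric(u) * (nG + 1) + v
  first <- !duplicated(key)
  eu <- u[first]; ev <- v[first]
  nE <- length(eu)
  pairId <- match(key, key[first])                  # raw edge -> unique pair

  # adjacency: node -> (neighbour, pair id); direction-agnostic by default
  if (respectDirection) {
    src <- a[ok]; tgt <- b[ok]
    fromN <- c(src, tgt[!dirAB]); toN <- c(tgt, src[!dirAB])
    eidN <- c(pairId, pairId[!dirAB])
  } else {
    fromN <- c(eu, ev); toN <- c(ev, eu)
    eidN <- c(seq_len(nE), seq_len(nE))
  }
  fac <- factor(fromN, levels = seq_len(nG))
  adjNbr <- split(toN, fac)
  adjEid <- split(eidN, fac)

  # candidate probe pairs per unique edge; most genes have one probe, so
  # single-probe edges take a vectorised fast path
  probesByGene <- split(seq_along(probes)[!is.na(probeGene)],
                        probeGene[!is.na(probeGene)])
  pg <- vector("list", nG)
  pg[as.integer(names(probesByGene))] <- probesByGene
  nProbes <- lengths(pg)
  firstProbe <- rep(NA_integer_, nG)
  firstProbe[nProbes > 0L] <- vapply(pg[nProbes > 0L], `[[`, 0L, 1L)
  simple <- nProbes[eu] == 1L & nProbes[ev] == 1L
  pairA1 <- firstProbe[eu[simple]]
  pairB1 <- firstProbe[ev[simple]]
  pairEdge1 <- which(simple)
  multi <- which(!simple)
  pairA2 <- pairB2 <- pairEdge2 <- vector("list", length(multi))
  for (k in seq_along(multi)) {
    e <- multi[k]
    pa <- pg[[eu[e]]]; pb <- pg[[ev[e]]]
    na <- length(pa); nb <- length(pb)
    pairA2[[k]] <- rep(pa, times = nb)
    pairB2[[k]] <- rep(pb, each = na)
    pairEdge2[[k]] <- rep.int(e, na * nb)
  }
  pairA <- c(pairA1, unlist(pairA2))
  pairB <- c(pairB1, unlist(pairB2))
  pairEdge <- c(pairEdge1, unlist(pairEdge2))
  edgeRows <- sort(unique(c(pairA, pairB)))         # probe rows used by edges
  pairPosA <- match(pairA, edgeRows)
  pairPosB <- match(pairB, edgeRows)
  # edges with a single candidate pair (fast path) vs multi-probe edges
  npairs <- tabulate(pairEdge, nE)
  single <- npairs == 1L
  singlePair <- match(which(single), pairEdge)
  # multi-probe edges: pad candidate pair rows into a matrix so the
  # per-edge |r| argmax is one max.col call instead of a loop
  multiEdgeIds <- which(!single)
  if (length(multiEdgeIds)) {
    mp <- max(npairs)
    o <- order(pairEdge)
    grp <- pairEdge[o]
    posInGrp <- sequence(npairs[npairs > 0L])
    multiMat <- matrix(NA_integer_, length(multiEdgeIds), mp)
    sel <- grp %in% multiEdgeIds
    multiMat[cbind(match(grp[sel], multiEdgeIds), posInGrp[sel])] <- o[sel]
  } else {
    multiMat <- matrix(NA_integer_, 0L, 0L)
  }

  list(X = X, samples = samples, inMask = labels == subtype,
       labels = labels, genes = genes, gidx = gidx, probeGene = probeGene,
       eu = eu, ev = ev, nE = nE, nG = nG,
       adjNbr = adjNbr, adjEid = adjEid,
       pairA = pairA, pairB = pairB,
       pairPosA = pairPosA, pairPosB = pairPosB, pairEdge = pairEdge,
       edgeRows = edgeRows, single = single, singlePair = singlePair,
       multiEdgeIds = multiEdgeIds, multiMat = multiMat)
}

# Vectorised Welch (or pooled) two-sample t-test, rows of X1 vs rows of X2.
# Zero variance in both groups gives p = 1 (statistic undefined).
.welchT <- function(X1, X2, pooled = FALSE) {
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- 1; tstat[degen] <- 0
  list(t = tstat, df = df, p = p, meanDiff = m1 - m2)
}

# k-th largest order statistic threshold for an upper-tail top fraction;
# an element qualifies iff it is >= the returned threshold.
.topFractionThreshold <- function(x, topFrac) {
  stopifnot(length(x) >= 1L, topFrac > 0, topFrac <= 1)
  k <- max(1L, floor(topFrac * length(x)))
  n <- length(x)
  if (k >= n) return(min(x))
  sort(x, partial = n - k + 1L)[n - k + 1L]
}

# rank-based probe selection: lowest topFracP p-values union highest
# topFracMedian median differences, restricted to positive median difference
.deSelect <- function(p, md, topFracP, topFracMedian) {
  P <- length(p)
  kP <- ceiling(topFracP * P)
  pCut <- unname(sort(p)[kP])
  selP <- p <= pCut
  # median rule keeps ceiling(frac*P) + ties, mirroring the p-value rule
  mdCut <- unname(sort(md, decreasing = TRUE)[ceiling(topFracMedian * P)])
  selM <- md >= mdCut
  pos <- md > 0
  list(selected = (selP | selM) & pos, selP = selP & pos, selM = selM & pos,
       pCut = pCut, mdCut = mdCut)
}

# One full expansion run on a sample subset / row permutation.
# seeds: gene symbols. Returns membership, reasons and the realised
# statistics. reason codes: 1 seed, 2 seed+DE, 3 DE, 4 coexpression-only.
.runExpansion <- function(ctx, seeds, sampleIdx = NULL, rowPerm = NULL,
                          topFracP = 0.02, topFracMedian = 0.01,
                          deltaTopFrac = 0.002,
                          fixedDeltaThreshold = NULL,
                          pooled = FALSE, strictBonferroni = FALSE,
                          bonferroniAlpha = 0.05,
                          keepStats = FALSE) {
  X <- ctx$X
  if (!is.null(rowPerm)) X <- X[rowPerm, , drop = FALSE]
  if (is.null(sampleIdx)) sampleIdx <- seq_len(ncol(X))
  inC <- sampleIdx[ctx$inMask[sampleIdx]]
  outC <- sampleIdx[!ctx$inMask[sampleIdx]]
  if (length(inC) < 2L || length(outC) < 2L)
    stop("both subtype and rest groups need >= 2 samples")
  X1 <- X[, inC, drop = FALSE]; X2 <- X[, outC, drop = FALSE]
  tt <- .welchT(X1, X2, pooled = pooled)
  md <- matrixStats::rowMedians(X1, na.rm = TRUE) -
        matrixStats::rowMedians(X2, na.rm = TRUE)
  sel <- .deSelect(tt$p, md, topFracP, topFracMedian)
  selected <- sel$selected
  if (strictBonferroni)
    selected <- selected & tt$p <= bonferroniAlpha / length(tt$p)
  deGene <- logical(ctx$nG)
  gsel <- ctx$probeGene[selected]
  deGene[gsel[!is.na(gsel)]] <- TRUE

  # edge differential correlations on the candidate probe pairs
  rows <- ctx$edgeRows
  Zin <- .rowStandardize(X1[rows, , drop = FALSE])
  Zout <- .rowStandardize(X2[rows, , drop = FALSE])
  riPair <- rowSums(Zin[ctx$pairPosA, , drop = FALSE] *
                    Zin[ctx$pairPosB, , drop = FALSE])
  pick <- .pickPairs(ctx, riPair)
  rIn <- riPair[pick]
  rOut <- rowSums(Zout[ctx$pairPosA[pick], , drop = FALSE] *
                  Zout[ctx$pairPosB[pick], , drop = FALSE])
  rIn[is.na(rIn)] <- 0; rOut[is.na(rOut)] <- 0   # degenerate (constant) side
  delta <- rIn - rOut
  thr <- if (is.null(fixedDeltaThreshold)) {
    if (ctx$nE) .topFractionThreshold(delta, deltaTopFrac) else Inf
  } else fixedDeltaThreshold
  qual <- delta >= thr

  # frontier expansion to the fixed point
  seeds <- toupper(seeds)
  seedIdx <- unname(ctx$gidx[seeds[seeds %in% ctx$genes]])
  extraSeeds <- setdiff(seeds, ctx$genes)
  bfs <- .bfs(ctx, seedIdx, deGene, qual)
  res <- list(member = bfs$member, reason = bfs$reason,
              extraSeeds = extraSeeds,
              deGene = deGene, deltaThreshold = thr)
  if (keepStats)
    res <- c(res, list(p = tt$p, medianDiff = md, selectedProbes = selected,
                       selectedBy = ifelse(sel$selP & sel$selM, "both",
                                    ifelse(sel$selP, "p",
                                    ifelse(sel$selM, "median", "none"))),
                       bonferroni = tt$p <= bonferroniAlpha / length(tt$p),
                       rIn = rIn, rOut = rOut, delta = delta, qual = qual,
                       pCut = sel$pCut, mdCut = sel$mdCut))
  res
}

# frontier fixed-point expansion: from seed indices, include neighbour v of
# member m when v is differentially expressed or (m differentially
# expressed and edge m--v qualifies by differential co-expression).
# reason codes: 1 seed, 2 seed+DE, 3 DE, 4 coexpression-only
.bfs <- function(ctx, seedIdx, deGene, qual) {
  member <- logical(ctx$nG)
  reason <- integer(ctx$nG)
  member[seedIdx] <- TRUE
  reason[seedIdx] <- ifelse(deGene[seedIdx], 2L, 1L)
  queue <- seedIdx
  head <- 1L
  while (head <= length(queue)) {
    m <- queue[head]; head <- head + 1L
    nbrs <- ctx$adjNbr[[m]]
    if (!length(nbrs)) next
    eids <- ctx$adjEid[[m]]
    mDE <- deGene[m]
    for (k in seq_along(nbrs)) {
      v <- nbrs[k]
      if (member[v]) next
      if (deGene[v]) {
        member[v] <- TRUE; reason[v] <- 3L; queue <- c(queue, v)
      } else if (mDE && qual[eids[k]]) {
        member[v] <- TRUE; reason[v] <- 4L; queue <- c(queue, v)
      }
    }
  }
  list(member = member, reason = reason)
}

# Precomputation for expression-randomisation permutation reps: per-row
# test statistics and the row-standardised group matrices are invariant
# under a permutation of the row labels, so each rep only re-indexes them.
# Zt holds both groups' standardised values sample-by-probe (transposed:
# column extraction is cheap), W the group indicator, so the in/out
# correlations of all probe pairs come from one product and one crossprod.
.permutationContext <- function(ctx, topFracP = 0.02,
                                topFracMedian = 0.01, pooled = FALSE) {
  inC <- which(ctx$inMask); outC <- which(!ctx$inMask)
  X1 <- ctx$X[, inC, drop = FALSE]; X2 <- ctx$X[, outC, drop = FALSE]
  tt <- .welchT(X1, X2, pooled = pooled)
  md <- matrixStats::rowMedians(X1, na.rm = TRUE) -
        matrixStats::rowMedians(X2, na.rm = TRUE)
  selRow <- .deSelect(tt$p, md, topFracP, topFracMedian)$selected
  Zin <- .rowStandardize(X1); Zout <- .rowStandardize(X2)
  if (nrow(ctx$X) <= 4000L) {
    # full probe-by-probe correlation matrices: permuted-edge correlations
    # become O(1) lookups per rep
    list(selRow = selRow, Rin = tcrossprod(Zin), Rout = tcrossprod(Zout))
  } else {
    Zt <- rbind(t(Zin), t(Zout))
    W <- cbind(rep(c(1, 0), c(length(inC), length(outC))),
               rep(c(0, 1), c(length(inC), length(outC))))
    list(selRow = selRow, Zt = Zt, W = W)
  }
}

# one expansion with permuted probe labels (rows keep their values, labels
# are reassigned: permuted row i carries the values of original row perm[i])
.runPermuted <- function(ctx, pctx, perm, seeds, deltaTopFrac = 0.002) {
  deGene <- logical(ctx$nG)
  gsel <- ctx$probeGene[pctx$selRow[perm]]
  deGene[gsel[!is.na(gsel)]] <- TRUE
  pa <- perm[ctx$pairA]; pb <- perm[ctx$pairB]
  if (!is.null(pctx$Rin)) {
    idx <- cbind(pa, pb)
    riPair <- pctx$Rin[idx]; roPair <- pctx$Rout[idx]
  } else {
    P <- pctx$Zt[, pa, drop = FALSE] * pctx$Zt[, pb, drop = FALSE]
    RS <- crossprod(P, pctx$W)
    riPair <- RS[, 1L]; roPair <- RS[, 2L]
  }
  pick <- .pickPairs(ctx, riPair)
  rIn <- riPair[pick]; rOut <- roPair[pick]
  rIn[is.na(rIn)] <- 0; rOut[is.na(rOut)] <- 0
  delta <- rIn - rOut
  thr <- if (ctx$nE) .topFractionThreshold(delta, deltaTopFrac) else Inf
  seeds <- toupper(seeds)
  seedIdx <- unname(ctx$gidx[seeds[seeds %in% ctx$genes]])
  bfs <- .bfs(ctx, seedIdx, deGene, delta >= thr)
  c(ctx$genes[bfs$member], setdiff(seeds, ctx$genes))
}

# representative probe pair per edge: single-probe edges directly, multi-
# probe edges by |r| argmax over their padded candidate matrix
.pickPairs <- function(ctx, riPair) {
  pick <- integer(ctx$nE)
  pick[ctx$single] <- ctx$singlePair
  if (length(ctx$multiEdgeIds)) {
    R <- abs(matrix(riPair[ctx$multiMat], nrow(ctx$multiMat)))
    R[is.na(R)] <- -Inf
    j <- max.col(R, ties.method = "first")
    pick[ctx$multiEdgeIds] <- ctx$multiMat[cbind(seq_along(j), j)]
  }
  pick
}

# rows scaled to zero mean, unit sum of squares, so that the Pearson
# correlation of two rows is the inner product; constant rows become NA
.rowStandardize <- function(M) {
  M <- M - rowMeans(M, na.rm = TRUE)
  ss <- sqrt(rowSums(M * M, na.rm = TRUE))
  ss[ss == 0] <- NA_real_
  M / ss
}

# member genes as symbols
.memberGenes <- function(ctx, run) {
  c(ctx$genes[run$member], run$extraSeeds)
}

# stratified subsample preserving subtype proportions: floor(frac * n)
# samples in total, allocated per class by largest remainder
.stratifiedSample <- function(labels, frac) {
  n <- length(labels)
  total <- floor(frac * n)
  classes <- split(seq_len(n), labels)
  raw <- vapply(classes, length, integer(1L)) * frac
  base <- pmin(floor(raw), vapply(classes, length, integer(1L)))
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    take <- rep(0L, length(classes))
    i <- 1L
    while (rem > 0 && i <= length(extra)) {
      j <- extra[i]
      if (base[j] + take[j] < length(classes[[j]])) {
        take[j] <- take[j] + 1L; rem <- rem - 1L
      }
      i <- i + 1L
    }
    base <- base + take
  }
  sort(unlist(lapply(seq_along(classes), function(j) {
    cl <- classes[[j]]
    if (base[j] >= length(cl)) cl else sample(cl, base[j])
  }), use.names = FALSE))
}
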