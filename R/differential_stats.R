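#' Probe-level subtype differential overexpression
#'
#' For each probe, a two-tailed Welch t-test (subtype vs all other samples)
#' and the median expression difference between the two groups. Probes are
#' selected by rank: the lowest \code{topFracP} of p-values (the t-test
#' criterion, with the Bonferroni-significance flag recorded per probe)
#' unioned with the highest \code{topFracMedian} of median differences (the
#' rescue criterion for probes with high within-group spread). Only
#' overexpression enters network expansion, so the union is restricted to
#' probes with positive median difference; tied boundary values are kept.
#' Selected probes are mapped to gene symbols via the cohort's probe map.
#'
#' @param cohort an [OmicsCohort-class].
#' @param subtype the subtype tested against the rest.
#' @param topFracP fraction of probes kept by p-value rank (default 0.02).
#' @param topFracMedian fraction kept by median-difference rank
#'   (default 0.01).
#' @param bonferroniAlpha family-wise level for the per-probe Bonferroni
#'   flag (default 0.05).
#' @param variant \code{"welch"} (default, unequal variances) or
#'   \code{"pooled"}.
#' @param strictBonferroni additionally require Bonferroni significance for
#'   selection.
#' @param samples optional subset of sample ids to use (defaults to all
#'   analysed samples).
#' @return a [DifferentialExpressionResult-class].
#' @export
differentialExpression <- function(cohort, subtype,
                                   topFracP = 0.02, topFracMedian = 0.01,
                                   bonferroniAlpha = 0.05,
                                   variant = c("welch", "pooled"),
                                   strictBonferroni = FALSE,
                                   samples = NULL) {
  stopifnot(is(cohort, "OmicsCohort"))
  variant <- match.arg(variant)
  use <- analysedSamples(cohort)
  use <- use[use %in% names(cohort@labels)]
  if (!is.null(samples)) use <- intersect(use, samples)
  grp <- as.character(cohort@labels[use]) == subtype
  if (sum(grp) < 2L || sum(!grp) < 2L)
    stop("both the subtype and the rest group need >= 2 samples")
  X <- cohort@expression[, use, drop = FALSE]
  X1 <- X[, grp, drop = FALSE]; X2 <- X[, !grp, drop = FALSE]
  tt <- .welchT(X1, X2, pooled = variant == "pooled")
  md <- matrixStats::rowMedians(X1, na.rm = TRUE) -
        matrixStats::rowMedians(X2, na.rm = TRUE)
  sel <- .deSelect(tt$p, md, topFracP, topFracMedian)
  bonf <- tt$p <= bonferroniAlpha / length(tt$p)
  selected <- sel$selected
  if (strictBonferroni) selected <- selected & bonf
  probes <- rownames(X)
  gene <- rep(NA_character_, length(probes))
  hit <- probes %in% names(cohort@probeMap)
  gene[hit] <- unname(cohort@probeMap[probes[hit]])
  selBy <- ifelse(sel$selP & sel$selM, "both",
           ifelse(sel$selP, "p", ifelse(sel$selM, "median", "none")))
  selBy[!selected] <- "none"
  tab <- data.frame(probe = probes, gene = gene, p_value = tt$p,
                    bonferroni_significant = bonf, median_diff = md,
                    selected_by = selBy, stringsAsFactors = FALSE)
  selGenes <- sort(unique(gene[selected & !is.na(gene)]))
  new("DifferentialExpressionResult", subtype = subtype, table = tab,
      selectedProbes = probes[selected], selectedGenes = selGenes,
      thresholds = c(p_cutoff = sel$pCut, median_cutoff = sel$mdCut,
                     top_frac_p = topFracP,
                     top_frac_median = topFracMedian,
                     bonferroni_alpha = bonferroniAlpha))
}

#' Differential co-expression of one network edge
#'
#' Pearson correlation of the two endpoint genes within the subtype's
#' samples (\code{r_in}) and over all remaining samples (\code{r_out});
#' \code{delta = r_in - r_out} is the edge's differential co-expression.
#' When a gene has several probes, the probe pair with the highest absolute
#' within-subtype correlation represents the edge (the same pair is used
#' for both groups so that the difference compares identical measurements).
#' A constant expression vector in either group makes that correlation
#' undefined; it is set to 0 and flagged.
#'
#' @param geneA,geneB endpoint gene symbols.
#' @param cohort an [OmicsCohort-class].
#' @param subtype the subtype of interest.
#' @param samples optional subset of sample ids.
#' @return one-row data.frame with columns \code{geneA}, \code{geneB},
#'   \code{probeA}, \code{probeB}, \code{r_in}, \code{r_out}, \code{delta},
#'   \code{degenerate}.
#' @export
edgeDifferentialCorrelation <- function(geneA, geneB, cohort, subtype,
                                        samples = NULL) {
  stopifnot(is(cohort, "OmicsCohort"))
  geneA <- toupper(geneA); geneB <- toupper(geneB)
  use <- analysedSamples(cohort)
  if (!is.null(samples)) use <- intersect(use, samples)
  grp <- as.character(cohort@labels[use]) == subtype
  if (sum(grp) < 3L || sum(!grp) < 3L)
    stop("both groups need >= 3 samples for edge correlations")
  probesOf <- function(g) {
    pr <- names(cohort@probeMap)[cohort@probeMap == g]
    pr[pr %in% rownames(cohort@expression)]
  }
  pa <- probesOf(geneA); pb <- probesOf(geneB)
  if (!length(pa) || !length(pb))
    stop("both genes need at least one probe with expression data")
  X <- cohort@expression[, use, drop = FALSE]
  corOr0 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    .pearson(x, y)
  }
  best <- c(NA_real_, NA_integer_, NA_integer_)
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    r <- corOr0(X[pa[i], grp], X[pb[j], grp])
    score <- if (is.na(r)) -Inf else abs(r)
    if (is.na(best[1L]) || score > best[1L]) best <- c(score, i, j)
  }
  i <- best[2L]; j <- best[3L]
  rin <- corOr0(X[pa[i], grp], X[pb[j], grp])
  rout <- corOr0(X[pa[i], !grp], X[pb[j], !grp])
  degenerate <- is.na(rin) || is.na(rout)
  if (is.na(rin)) rin <- 0
  if (is.na(rout)) rout <- 0
  data.frame(geneA = geneA, geneB = geneB,
             probeA = pa[i], probeB = pb[j],
             r_in = rin, r_out = rout, delta = rin - rout,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Differential co-expression of every network edge
#'
#' Computes \code{r_in}, \code{r_out} and \code{delta} for all unique gene
#' pairs of the network space whose endpoints have expression data. This is
#' the distribution from which the global co-expression threshold (top
#' \code{topFrac} of deltas) is taken and held fixed during expansion.
#'
#' @param net a [NetworkSpace-class].
#' @param cohort an [OmicsCohort-class].
#' @param subtype the subtype of interest.
#' @param topFrac upper-tail fraction defining qualification
#'   (default 0.002).
#' @return data.frame with one row per unique network gene pair: columns
#'   \code{geneA}, \code{geneB}, \code{r_in}, \code{r_out}, \code{delta},
#'   \code{qualifies}; the realised threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
edgeDeltaTable <- function(net, cohort, subtype, topFrac = 0.002) {
  ctx <- .expansionContext(net, cohort, subtype)
  run <- .runExpansion(ctx, seeds = character(0), deltaTopFrac = topFrac,
                       keepStats = TRUE)
  out <- data.frame(geneA = ctx$genes[ctx$eu], geneB = ctx$genes[ctx$ev],
                    r_in = run$rIn, r_out = run$rOut, delta = run$delta,
                    qualifies = run$qual, stringsAsFactors = FALSE)
  attr(out, "threshold") <- run$deltaThreshold
  out
}

#' Upper-tail qualification threshold for differential correlations
#'
#' The cutoff such that the top \code{topFrac} of the delta distribution
#' qualifies: the k-th largest value with \code{k = max(1,
#' floor(topFrac * N))}. An edge qualifies iff its delta is greater than or
#' equal to the threshold, so boundary ties qualify too.
#'
#' @param deltas numeric vector of differential correlations.
#' @param topFrac upper-tail fraction (default 0.002).
#' @return the threshold value.
#' @examples
#' coexpressionThreshold(c(rep(0, 1000), 1.5, 1.5))
#' @export
coexpressionThreshold <- function(deltas, topFrac = 0.002) {
  .topFractionThreshold(deltas, topFrac)
}
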