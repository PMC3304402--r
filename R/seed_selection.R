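#' Select subtype-specific seed genes
#'
#' Seed genes anchor the driver-network expansion: genes ranking in the top
#' \code{topFracCNA} of the subtype-average CNA score AND in the top
#' \code{topFracCorr} of the pooled CNA-expression correlation. Ranking over
#' the shared gene universe of the two inputs; cutoffs use
#' \code{ceiling(frac * N)} positions and genes tied with the boundary value
#' are all retained.
#'
#' @param scores named numeric vector: subtype-average CNA score per gene
#'   (see [averageCNAScore()]).
#' @param correlations named numeric vector: pooled CNA-expression
#'   correlation per gene (see [cnaExprCorrelation()]).
#' @param subtype subtype name recorded in the result.
#' @param topFracCNA fraction of the universe retained by CNA score
#'   (default 0.05).
#' @param topFracCorr fraction retained by correlation (default 0.10).
#' @param mode \code{"absolute"} ranks by |score| so that recurrent
#'   deletions can seed networks too (default); \code{"amplification"}
#'   ranks by signed score descending, amplification-only.
#' @param corrRank \code{"signed"} (default; amplification should raise
#'   expression) or \code{"absolute"} ranking of the correlation filter.
#' @return a [SeedSet-class]; empty (with a warning) when the two top lists
#'   do not intersect.
#' @examples
#' sc <- stats::setNames(seq(1, 0, length.out = 100), paste0("G", 1:100))
#' rr <- stats::setNames(seq(1, 0, length.out = 100), paste0("G", 1:100))
#' selectSeeds(sc, rr, "TNBC")
#' @export
selectSeeds <- function(scores, correlations, subtype = "subtype",
                        topFracCNA = 0.05, topFracCorr = 0.10,
                        mode = c("absolute", "amplification"),
                        corrRank = c("signed", "absolute")) {
  mode <- match.arg(mode)
  corrRank <- match.arg(corrRank)
  stopifnot(topFracCNA > 0, topFracCNA <= 1,
            topFracCorr > 0, topFracCorr <= 1)
  universe <- intersect(names(scores), names(correlations))
  if (!length(universe)) stop("scores and correlations share no genes")
  sc <- scores[universe]
  rr <- correlations[universe]
  scKey <- if (mode == "absolute") abs(sc) else sc
  rrKey <- if (corrRank == "absolute") abs(rr) else rr
  top <- function(key, frac) {
    k <- ceiling(frac * length(key))
    cutoff <- sort(key, decreasing = TRUE)[k]
    names(key)[key >= cutoff]
  }
  seeds <- intersect(top(scKey, topFracCNA), top(rrKey, topFracCorr))
  if (!length(seeds))
    warning("no gene passed both rank filters; empty seed set")
  new("SeedSet", subtype = subtype,
      seeds = data.frame(gene = seeds,
                         avg_cna_score = unname(sc[seeds]),
                         cna_expr_corr = unname(rr[seeds]),
                         stringsAsFactors = FALSE))
}

#' Build a SeedSet from an explicit gene list
#'
#' Supports importing seeds selected on another cohort (or planted truth)
#' into an expansion run; scores/correlations are recorded as NA when
#' unknown.
#'
#' @param genes character vector of seed gene symbols.
#' @param subtype subtype name.
#' @param avgCnaScore,cnaExprCorr optional per-gene annotation vectors.
#' @return a [SeedSet-class].
#' @export
seedSet <- function(genes, subtype = "subtype",
                    avgCnaScore = NA_real_, cnaExprCorr = NA_real_) {
  genes <- unique(toupper(genes))
  new("SeedSet", subtype = subtype,
      seeds = data.frame(gene = genes,
                         avg_cna_score = rep_len(avgCnaScore, length(genes)),
                         cna_expr_corr = rep_len(cnaExprCorr, length(genes)),
                         stringsAsFactors = FALSE))
}

#' Read / write seed tables
#'
#' Tab-separated with columns \code{gene}, \code{subtype},
#' \code{avg_cna_score}, \code{cna_expr_corr}.
#'
#' @param x a [SeedSet-class].
#' @param path file path.
#' @return \code{readSeedSet}: a [SeedSet-class]; \code{writeSeedSet}:
#'   \code{path}, invisibly.
#' @name seed-io
NULL

#' @rdname seed-io
#' @export
writeSeedSet <- function(x, path) {
  stopifnot(is(x, "SeedSet"))
  d <- x@seeds
  d$subtype <- x@subtype
  utils::write.table(d[, c("gene", "subtype", "avg_cna_score",
                           "cna_expr_corr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname seed-io
#' @export
readSeedSet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  subtype <- if (nrow(d)) as.character(d$subtype[1L]) else "subtype"
  new("SeedSet", subtype = subtype,
      seeds = data.frame(gene = toupper(d$gene),
                         avg_cna_score = as.numeric(d$avg_cna_score),
                         cna_expr_corr = as.numeric(d$cna_expr_corr),
                         stringsAsFactors = FALSE))
}

#' One-call seed selection from a cohort
#'
#' Convenience wrapper: discretises the CNA matrix if needed, computes the
#' subtype-average CNA score and the pooled CNA-expression correlation, and
#' intersects the two top lists.
#'
#' @param cohort an [OmicsCohort-class].
#' @param subtype subtype name.
#' @param ... passed to [selectSeeds()].
#' @inheritParams cnaExprCorrelation
#' @return a [SeedSet-class].
#' @export
selectSeedsFromCohort <- function(cohort, subtype,
                                  gainThreshold = 0.3, lossThreshold = -0.3,
                                  useDiscrete = TRUE, ...) {
  stopifnot(is(cohort, "OmicsCohort"))
  disc <- .discreteCalls(cohort, gainThreshold, lossThreshold)
  samples <- analysedSamples(cohort)
  scores <- averageCNAScore(disc[, samples, drop = FALSE],
                            cohort@labels, subtype)
  correlations <- suppressMessages(
    cnaExprCorrelation(cohort, useDiscrete = useDiscrete,
                       gainThreshold = gainThreshold,
                       lossThreshold = lossThreshold))
  selectSeeds(scores, correlations, subtype, ...)
}
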