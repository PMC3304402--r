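#' siRNA screen scoring
#'
#' A screen table holds one viability measurement per row, with columns
#' \code{gene}, \code{sirna_id}, \code{cell_line}, \code{group}
#' (\code{"target_subtype"} or \code{"other"}), \code{replicate},
#' \code{viability} (positive) and \code{is_control} (logical; control rows
#' carry the non-targeting control measurements of their cell line).
#'
#' @param path tab-separated screen file.
#' @return data.frame.
#' @export
readScreen <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$is_control <- as.logical(d$is_control)
  d$viability <- as.numeric(d$viability)
  d
}

# one-sided Welch t for a viability reduction vs control; p near 0 means
# the siRNA lowered viability
.knockdownP <- function(sirnaVals, controlVals) {
  n1 <- length(sirnaVals); n2 <- length(controlVals)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per siRNA and control")
  m1 <- mean(sirnaVals); m2 <- mean(controlVals)
  v1 <- stats::var(sirnaVals); v2 <- stats::var(controlVals)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(1)                 # no variation, no evidence
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  stats::pt(tstat, df)                    # lower tail: reduction
}

#' Per-gene, per-cell-line validation call
#'
#' A gene is functionally validated in a cell line when at least
#' \code{minSirnas} of its siRNAs each show a significant one-sided
#' viability reduction versus the cell line's control at level
#' \code{alpha} (one-sided Welch t-test of the siRNA replicates against
#' the control replicates).
#'
#' @param screen screen data.frame (see [readScreen()]).
#' @param gene gene symbol.
#' @param cellLine cell line identifier.
#' @param alpha significance level.
#' @param minSirnas minimum number of significant siRNAs (default 2).
#' @return logical.
#' @export
geneValidated <- function(screen, gene, cellLine, alpha,
                          minSirnas = 2L) {
  ctl <- screen$viability[screen$is_control &
                          screen$cell_line == cellLine]
  if (!length(ctl)) stop("no control measurements for cell line ", cellLine)
  rows <- screen[!screen$is_control & screen$gene == gene &
                 screen$cell_line == cellLine, , drop = FALSE]
  if (!nrow(rows)) return(FALSE)
  ps <- vapply(split(rows$viability, rows$sirna_id),
               .knockdownP, numeric(1L), controlVals = ctl)
  sum(ps <= alpha) >= minSirnas
}

#' Group viability score
#'
#' For every gene of \code{geneSet}, the fraction of the group's cell lines
#' in which the gene is validated (see [geneValidated()]); the score is the
#' mean of these fractions over genes. Higher scores indicate greater
#' functional importance of the gene set in that cell-line group.
#'
#' @param screen screen data.frame.
#' @param geneSet character vector of genes (must be tested in the group).
#' @param group \code{"target_subtype"} or \code{"other"}.
#' @param alpha significance level.
#' @param minSirnas minimum significant siRNAs per validation call.
#' @return numeric score in [0, 1].
#' @export
viabilityScore <- function(screen, geneSet, group = "target_subtype",
                           alpha = 0.05, minSirnas = 2L) {
  geneSet <- unique(geneSet)
  if (!length(geneSet)) stop("empty gene set")
  lines <- unique(screen$cell_line[screen$group == group])
  fractions <- vapply(geneSet, function(g) {
    tested <- lines[lines %in%
                    screen$cell_line[!screen$is_control &
                                     screen$gene == g]]
    if (!length(tested))
      stop("gene ", g, " was not tested in any ", group, " cell line")
    mean(vapply(tested, function(cl)
      geneValidated(screen, g, cl, alpha, minSirnas), logical(1L)))
  }, numeric(1L))
  mean(fractions)
}

#' Viability score across a range of significance thresholds
#'
#' Evaluates [viabilityScore()] for each threshold, enabling the comparison
#' of gene-set functional importance curves (e.g. driver-network members vs
#' genes selected by differential expression alone) without committing to a
#' single alpha. Scores are monotone non-decreasing in alpha.
#'
#' @inheritParams viabilityScore
#' @param alphas increasing numeric vector of significance levels.
#' @return data.frame with columns \code{alpha}, \code{score}.
#' @export
viabilityCurve <- function(screen, geneSet, group = "target_subtype",
                           alphas = c(0.001, 0.005, 0.01, 0.05, 0.1,
                                      0.2, 0.5),
                           minSirnas = 2L) {
  stopifnot(!is.unsorted(alphas))
  data.frame(alpha = alphas,
             score = vapply(alphas, function(a)
               viabilityScore(screen, geneSet, group, a, minSirnas),
               numeric(1L)))
}
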