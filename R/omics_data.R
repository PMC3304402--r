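#' Construct an OmicsCohort
#'
#' Bundles probe-level expression, a probe-to-gene map, gene-level copy
#' number and subtype labels into one validated [OmicsCohort-class].
#' Probes absent from the map are kept in the matrix but never analysed
#' (reported via a message); probes with more than \code{maxMissing} missing
#' values are dropped. Analyses run on the intersection of expression and
#' CNA sample ids, all of which must carry a label.
#'
#' @param expression numeric matrix, probes x samples (log-scale), with
#'   probe rownames and sample colnames.
#' @param probeMap named character vector, probe id -> gene symbol.
#' @param cna numeric matrix, genes x samples.
#' @param labels named character/factor vector, sample id -> subtype.
#' @param cnaDiscrete logical; \code{TRUE} when \code{cna} already holds
#'   -1/0/1 calls. Default guesses from the matrix content.
#' @param maxMissing maximum tolerated fraction of missing values per probe.
#' @return an [OmicsCohort-class].
#' @export
OmicsCohort <- function(expression, probeMap, cna, labels,
                        cnaDiscrete = all(cna %in% c(-1, 0, 1)),
                        maxMissing = 0.2) {
  expression <- as.matrix(expression)
  cna <- as.matrix(cna)
  probeMap <- stats::setNames(toupper(as.character(probeMap)),
                              names(probeMap))
  rownames(cna) <- toupper(rownames(cna))
  miss <- rowMeans(is.na(expression))
  if (any(miss > maxMissing)) {
    message("dropped ", sum(miss > maxMissing), " probe(s) with > ",
            maxMissing * 100, "% missing values")
    expression <- expression[miss <= maxMissing, , drop = FALSE]
  }
  unmapped <- sum(!rownames(expression) %in% names(probeMap))
  if (unmapped)
    message(unmapped, " probe(s) have no gene mapping and are ignored ",
            "in gene-level analyses")
  labels <- stats::setNames(factor(as.character(labels)), names(labels))
  new("OmicsCohort", expression = expression, probeMap = probeMap,
      cna = cna, cnaDiscrete = isTRUE(cnaDiscrete), labels = labels)
}

#' Samples analysed in a cohort
#'
#' The intersection of expression and CNA sample ids: the samples on which
#' all cohort statistics are computed.
#'
#' @param cohort an [OmicsCohort-class].
#' @return character vector of sample ids.
#' @export
analysedSamples <- function(cohort) {
  stopifnot(is(cohort, "OmicsCohort"))
  intersect(colnames(cohort@expression), colnames(cohort@cna))
}

#' Discretise a continuous copy-number matrix
#'
#' Thresholds continuous log-ratios into -1 (loss), 0 (neutral) and
#' +1 (gain) calls: an entry is 1 when its value is at least
#' \code{gainThreshold}, -1 when at most \code{lossThreshold}, 0 otherwise.
#'
#' @param cna numeric matrix of continuous log-ratios (genes x samples).
#' @param gainThreshold positive gain cutoff (default 0.3 on log2 ratios).
#' @param lossThreshold negative loss cutoff (default -0.3).
#' @return integer-valued matrix of the same shape containing only -1/0/1.
#' @examples
#' m <- matrix(c(0.5, -0.5, 0.1), 3, 1,
#'             dimnames = list(c("A", "B", "C"), "s1"))
#' discretizeCNA(m)
#' @export
discretizeCNA <- function(cna, gainThreshold = 0.3, lossThreshold = -0.3) {
  if (!(gainThreshold > 0) || !(lossThreshold < 0))
    stop("need gainThreshold > 0 > lossThreshold")
  cna <- as.matrix(cna)
  out <- matrix(0, nrow(cna), ncol(cna), dimnames = dimnames(cna))
  out[cna >= gainThreshold] <- 1
  out[cna <= lossThreshold] <- -1
  out[is.na(cna)] <- NA
  out
}

# discrete CNA calls of a cohort, discretizing on the fly when continuous
.discreteCalls <- function(cohort, gainThreshold = 0.3,
                           lossThreshold = -0.3) {
  if (cohort@cnaDiscrete) cohort@cna
  else discretizeCNA(cohort@cna, gainThreshold, lossThreshold)
}

#' Subtype-average copy-number score
#'
#' Per-gene arithmetic mean of discrete -1/0/1 calls over the samples of one
#' subtype. A gene amplified in every sample of the subtype scores 1.
#'
#' @param disc discrete CNA matrix (genes x samples, values in -1/0/1).
#' @param labels named factor/character vector, sample id -> subtype.
#' @param subtype the subtype to average over.
#' @return named numeric vector in [-1, 1], one entry per gene.
#' @export
averageCNAScore <- function(disc, labels, subtype) {
  disc <- as.matrix(disc)
  if (!all(disc %in% c(-1, 0, 1, NA)))
    stop("disc must be a discrete -1/0/1 matrix; see discretizeCNA()")
  samples <- intersect(colnames(disc), names(labels))
  samples <- samples[as.character(labels[samples]) == subtype]
  if (!length(samples)) stop("subtype ", subtype, " has no samples")
  rowMeans(disc[, samples, drop = FALSE], na.rm = TRUE)
}

#' Pooled copy-number / expression correlation
#'
#' For every gene with both copy-number and (via the probe map) expression
#' data, the Pearson correlation between its discrete CNA calls and its
#' expression across all analysed samples, pooling all subtypes. For
#' multi-probe genes the representative probe is the one with the highest
#' absolute correlation. Genes with a constant CNA vector (correlation
#' undefined and uninformative) or fewer than \code{minSamples} paired
#' samples are omitted.
#'
#' @param cohort an [OmicsCohort-class].
#' @param useDiscrete correlate against discrete calls (default) rather than
#'   continuous log-ratios.
#' @param gainThreshold,lossThreshold discretisation cutoffs applied when
#'   the cohort's CNA matrix is continuous.
#' @param minSamples minimum paired samples per gene (default 3).
#' @return named numeric vector of correlations in [-1, 1].
#' @export
cnaExprCorrelation <- function(cohort, useDiscrete = TRUE,
                               gainThreshold = 0.3, lossThreshold = -0.3,
                               minSamples = 3L) {
  stopifnot(is(cohort, "OmicsCohort"))
  samples <- analysedSamples(cohort)
  cnaM <- if (useDiscrete) .discreteCalls(cohort, gainThreshold, lossThreshold)
          else cohort@cna
  cnaM <- cnaM[, samples, drop = FALSE]
  probes <- rownames(cohort@expression)
  mapped <- probes[probes %in% names(cohort@probeMap)]
  geneOf <- unname(cohort@probeMap[mapped])
  keep <- geneOf %in% rownames(cnaM)
  mapped <- mapped[keep]; geneOf <- geneOf[keep]
  genes <- unique(geneOf)
  expr <- cohort@expression[mapped, samples, drop = FALSE]
  cvals <- cnaM[geneOf, , drop = FALSE]
  # pairwise-complete, vectorised over the complete-data fast path
  anyNA <- rowSums(is.na(expr)) > 0 | rowSums(is.na(cvals)) > 0
  r <- rep(NA_real_, length(mapped))
  if (any(!anyNA)) {
    i <- which(!anyNA)
    ec <- expr[i, , drop = FALSE] - rowMeans(expr[i, , drop = FALSE])
    cc <- cvals[i, , drop = FALSE] - rowMeans(cvals[i, , drop = FALSE])
    den <- sqrt(rowSums(ec^2) * rowSums(cc^2))
    r[i] <- ifelse(den > 0, rowSums(ec * cc) / den, NA_real_)
  }
  for (j in which(anyNA)) {
    use <- !is.na(expr[j, ]) & !is.na(cvals[j, ])
    if (sum(use) < minSamples) next
    if (stats::sd(expr[j, use]) == 0 || stats::sd(cvals[j, use]) == 0) next
    r[j] <- .pearson(cvals[j, use], expr[j, use])
  }
  if (ncol(expr) < minSamples) r[] <- NA_real_
  ok <- !is.na(r)
  out <- numeric(0)
  if (any(ok)) {
    pickBest <- vapply(split(which(ok), geneOf[ok]),
                       function(i) i[which.max(abs(r[i]))], integer(1L))
    out <- stats::setNames(r[pickBest], names(pickBest))
  }
  omitted <- length(genes) - length(out)
  if (omitted)
    message(omitted, " gene(s) omitted (constant vector or < ",
            minSamples, " paired samples)")
  out
}

# plain Pearson on complete vectors (no stats::cor: that is the test oracle)
.pearson <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sum(x * y) / sqrt(sum(x * x) * sum(y * y))
}

#' Collapse probes to one row per gene
#'
#' Selects a single representative probe per gene, either the most variable
#' probe (\code{"maxVariance"}) or the probe with the highest absolute
#' Pearson correlation against a fixed partner vector
#' (\code{"maxAbsCorrelation"}, the rule used in correlation contexts).
#' Output rows are always rows of the input; no values are invented.
#'
#' @param expr numeric matrix, probes x samples.
#' @param probeMap named character vector, probe id -> gene symbol.
#' @param rule \code{"maxVariance"} or \code{"maxAbsCorrelation"}.
#' @param partner numeric vector over the samples of \code{expr}; required
#'   for \code{rule = "maxAbsCorrelation"}.
#' @return gene-level matrix with gene rownames and an attribute
#'   \code{"probe"}: the chosen probe id per gene.
#' @export
collapseProbes <- function(expr, probeMap,
                           rule = c("maxVariance", "maxAbsCorrelation"),
                           partner = NULL) {
  rule <- match.arg(rule)
  expr <- as.matrix(expr)
  if (!length(probeMap)) stop("empty probe map")
  mapped <- rownames(expr)[rownames(expr) %in% names(probeMap)]
  if (!length(mapped)) stop("no probe of expr is present in probeMap")
  geneOf <- probeMap[mapped]
  if (rule == "maxAbsCorrelation") {
    if (is.null(partner) || length(partner) != ncol(expr))
      stop("maxAbsCorrelation needs a partner vector over the samples")
    crit <- apply(expr[mapped, , drop = FALSE], 1L, function(v) {
      if (stats::sd(v) == 0 || stats::sd(partner) == 0) return(-Inf)
      abs(.pearson(v, partner))
    })
  } else {
    crit <- matrixStats::rowVars(expr[mapped, , drop = FALSE])
  }
  pick <- vapply(split(seq_along(mapped), geneOf),
                 function(i) i[which.max(crit[i])], integer(1L))
  out <- expr[mapped[pick], , drop = FALSE]
  rownames(out) <- names(pick)
  attr(out, "probe") <- stats::setNames(mapped[pick], names(pick))
  out
}

#' Read / write cohort component tables
#'
#' Plain tab-separated interchange formats: expression (first column
#' \code{probe_id}, then one column per sample), probe map (2 columns:
#' \code{probe_id}, \code{gene_symbol}), CNA (first column
#' \code{gene_symbol}, then samples) and labels (2 columns:
#' \code{sample_id}, \code{subtype}).
#'
#' @param path file path.
#' @return \code{readExpressionMatrix}/\code{readCNAMatrix}: numeric matrix;
#'   \code{readProbeMap}: named character vector; \code{readSubtypeLabels}:
#'   named factor.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
readExpressionMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname cohort-io
#' @export
readCNAMatrix <- function(path) {
  m <- readExpressionMatrix(path)
  rownames(m) <- toupper(rownames(m))
  m
}

#' @rdname cohort-io
#' @export
readProbeMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(toupper(as.character(d[[2L]])), as.character(d[[1L]]))
}

#' @rdname cohort-io
#' @export
readSubtypeLabels <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(factor(as.character(d[[2L]])), as.character(d[[1L]]))
}

#' Write an OmicsCohort to a directory of tab-separated tables
#'
#' Writes \code{expression.tsv}, \code{probe_map.tsv}, \code{cna.tsv} and
#' \code{labels.tsv} in the formats read back by [readCohort()].
#'
#' @param cohort an [OmicsCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "OmicsCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, first, file)
    utils::write.table(data.frame(first = rownames(x), x,
                                  check.names = FALSE),
                       file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE,
                       col.names = c(first, colnames(x)))
  wt(cohort@expression, "probe_id", "expression.tsv")
  wt(cohort@cna, "gene_symbol", "cna.tsv")
  utils::write.table(data.frame(probe_id = names(cohort@probeMap),
                                gene_symbol = cohort@probeMap),
                     file.path(dir, "probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(cohort@labels),
                                subtype = as.character(cohort@labels)),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an OmicsCohort from a directory written by [writeCohort()]
#'
#' @param dir directory containing \code{expression.tsv},
#'   \code{probe_map.tsv}, \code{cna.tsv} and \code{labels.tsv}.
#' @return an [OmicsCohort-class].
#' @export
readCohort <- function(dir) {
  OmicsCohort(readExpressionMatrix(file.path(dir, "expression.tsv")),
              readProbeMap(file.path(dir, "probe_map.tsv")),
              readCNAMatrix(file.path(dir, "cna.tsv")),
              readSubtypeLabels(file.path(dir, "labels.tsv")))
}
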