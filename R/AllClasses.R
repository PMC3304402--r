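#' @import methods
NULL

#' NetworkSpace: a combined directed/undirected interactome
#'
#' Holds the merged network space on which driver-networks are expanded:
#' protein-protein interactions (undirected) together with
#' transcription-regulatory and signalling interactions (directed).
#' Edges are deduplicated per (gene pair, provenance); an undirected
#' \code{ppi} edge and a directed \code{tf} edge between the same pair of
#' genes coexist as distinct edges. Self-loops are never stored.
#'
#' @slot edges data.frame with columns \code{source}, \code{target}
#'   (uppercase gene symbols), \code{directed} (logical) and
#'   \code{provenance} (one of \code{"ppi"}, \code{"tf"},
#'   \code{"signalling"}).
#' @slot nodes character vector of all gene symbols occurring as an edge
#'   endpoint.
#'
#' @seealso [mergeNetworks()], [readEdgeList()], [neighborGenes()]
#' @export
setClass("NetworkSpace",
         representation(edges = "data.frame", nodes = "character"))

setValidity("NetworkSpace", function(object) {
  ed <- object@edges
  need <- c("source", "target", "directed", "provenance")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (!all(ed$provenance %in% c("ppi", "tf", "signalling")))
      return("provenance must be one of ppi/tf/signalling")
    if (any(ed$provenance == "ppi" & ed$directed))
      return("ppi edges must be undirected")
    if (any(ed$provenance != "ppi" & !ed$directed))
      return("tf/signalling edges must be directed")
    if (any(ed$source == ed$target))
      return("self-loops are not allowed")
    if (!all(c(ed$source, ed$target) %in% object@nodes))
      return("every edge endpoint must be in nodes")
    if (anyDuplicated(.edgeKey(ed)))
      return("duplicate (pair, provenance) edges")
  }
  TRUE
})

# dedup key: unordered pair for undirected edges, ordered for directed
.edgeKey <- function(ed) {
  a <- ifelse(ed$directed, ed$source, pmin(ed$source, ed$target))
  b <- ifelse(ed$directed, ed$target, pmax(ed$source, ed$target))
  paste(a, b, ed$provenance, sep = "\r")
}

#' OmicsCohort: aligned expression, copy-number and subtype labels
#'
#' Container for one cohort: a probe-level log-scale expression matrix, a
#' probe-to-gene map, a gene-level copy-number matrix (continuous log-ratios
#' or discrete -1/0/1 calls) and mutually exclusive subtype labels. All
#' analyses run on the intersection of expression and copy-number sample
#' identifiers that carry a label.
#'
#' @slot expression numeric matrix, probes x samples, rownames are probe ids.
#' @slot probeMap named character vector mapping probe id -> gene symbol
#'   (many probes per gene allowed).
#' @slot cna numeric matrix, genes x samples; discrete matrices contain only
#'   -1, 0, 1.
#' @slot cnaDiscrete logical, whether \code{cna} holds discrete calls.
#' @slot labels named factor, sample id -> subtype.
#'
#' @seealso [OmicsCohort()], [discretizeCNA()], [cnaExprCorrelation()]
#' @export
setClass("OmicsCohort",
         representation(expression = "matrix", probeMap = "character",
                        cna = "matrix", cnaDiscrete = "logical",
                        labels = "factor"))

setValidity("OmicsCohort", function(object) {
  if (is.null(rownames(object@expression)) || is.null(colnames(object@expression)))
    return("expression must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(object@expression)))
    return("probe ids must be unique")
  if (is.null(rownames(object@cna)) || is.null(colnames(object@cna)))
    return("cna must have gene rownames and sample colnames")
  if (is.null(names(object@probeMap)) || any(!nzchar(object@probeMap)))
    return("probeMap must be a named vector with non-empty gene symbols")
  if (isTRUE(object@cnaDiscrete) &&
      !all(object@cna %in% c(-1, 0, 1)))
    return("discrete CNA matrix may only contain -1, 0, 1")
  shared <- intersect(colnames(object@expression), colnames(object@cna))
  if (!length(shared))
    return("expression and cna share no sample ids")
  if (is.null(names(object@labels)))
    return("labels must be named by sample id")
  if (!all(shared %in% names(object@labels)))
    return("every analysed sample (expression/cna intersection) needs a label")
  TRUE
})

#' SeedSet: subtype-specific amplification-anchored seed genes
#'
#' @slot subtype character scalar.
#' @slot seeds data.frame with columns \code{gene}, \code{avg_cna_score},
#'   \code{cna_expr_corr}; one row per seed gene.
#'
#' @seealso [selectSeeds()]
#' @export
setClass("SeedSet",
         representation(subtype = "character", seeds = "data.frame"))

setValidity("SeedSet", function(object) {
  need <- c("gene", "avg_cna_score", "cna_expr_corr")
  if (!all(need %in% names(object@seeds)))
    return(paste("seeds must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@seeds$gene)) return("duplicate seed genes")
  TRUE
})

#' DifferentialExpressionResult: probe-level subtype-vs-rest selection
#'
#' Result of the differential-overexpression criterion: per-probe Welch
#' t-test p-values and median differences, the rank-selected probe sets
#' (lowest top fraction of p-values union highest top fraction of median
#' differences, restricted to positive median difference) and their gene
#' image.
#'
#' @slot subtype character scalar.
#' @slot table data.frame with columns \code{probe}, \code{gene},
#'   \code{p_value}, \code{bonferroni_significant}, \code{median_diff},
#'   \code{selected_by} (\code{"p"}, \code{"median"}, \code{"both"} or
#'   \code{"none"}).
#' @slot selectedProbes character vector of selected probe ids.
#' @slot selectedGenes character vector, gene image of selected probes.
#' @slot thresholds named numeric vector: realised p-value cutoff, median
#'   cutoff and the top fractions used.
#'
#' @seealso [differentialExpression()]
#' @export
setClass("DifferentialExpressionResult",
         representation(subtype = "character", table = "data.frame",
                        selectedProbes = "character",
                        selectedGenes = "character",
                        thresholds = "numeric"))

#' DriverNetwork: an expanded subtype driver-network
#'
#' @slot subtype character scalar.
#' @slot members data.frame with columns \code{gene}, \code{is_seed},
#'   \code{inclusion_reason} (\code{seed}, \code{seed+differential_expression},
#'   \code{differential_expression}, \code{coexpression_only}) and
#'   \code{membership_frequency} (1 for single-run networks; fraction of
#'   resamples otherwise).
#' @slot edges data.frame: induced interactome edges among members with
#'   columns \code{source}, \code{target}, \code{directed},
#'   \code{provenance}, \code{r_in}, \code{r_out}, \code{delta}.
#' @slot deltaThreshold numeric, realised differential co-expression cutoff
#'   (NA when not computed).
#'
#' @seealso [expandDriverNetwork()], [resampledDriverNetwork()]
#' @export
setClass("DriverNetwork",
         representation(subtype = "character", members = "data.frame",
                        edges = "data.frame", deltaThreshold = "numeric"))

setValidity("DriverNetwork", function(object) {
  need <- c("gene", "is_seed", "inclusion_reason", "membership_frequency")
  if (!all(need %in% names(object@members)))
    return(paste("members must have columns", paste(need, collapse = ", ")))
  mf <- object@members$membership_frequency
  if (length(mf) && (any(mf < 0) || any(mf > 1)))
    return("membership_frequency must lie in [0, 1]")
  TRUE
})

#' NullDistribution: randomisation null for cross-cohort overlap
#'
#' @slot scheme \code{"seed_randomisation"} or
#'   \code{"expression_randomisation"}.
#' @slot overlaps numeric vector of normalised overlaps, one per rep.
#' @slot observed numeric, the observed normalised overlap (NA if not
#'   supplied).
#' @slot pValue numeric, add-one empirical p-value of the observed value.
#' @slot reps integer.
#'
#' @seealso [expressionRandomizationNull()], [seedRandomizationNull()],
#'   [empiricalPValue()]
#' @export
setClass("NullDistribution",
         representation(scheme = "character", overlaps = "numeric",
                        observed = "numeric", pValue = "numeric",
                        reps = "integer"))

setValidity("NullDistribution", function(object) {
  if (!object@scheme %in% c("seed_randomisation", "expression_randomisation"))
    return("unknown randomisation scheme")
  if (length(object@overlaps) != object@reps)
    return("length(overlaps) must equal reps")
  if (any(object@overlaps < 0 | object@overlaps > 1))
    return("overlaps must lie in [0, 1]")
  TRUE
})
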