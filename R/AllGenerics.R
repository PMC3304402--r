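#' Accessors for driverSubnets classes
#'
#' Small accessor generics: \code{networkNodes} and \code{networkEdges} for
#' [NetworkSpace-class], \code{seedGenes} for [SeedSet-class],
#' \code{networkMembers} and \code{memberGenes} for [DriverNetwork-class],
#' \code{subtypeOf} for objects tied to one subtype.
#'
#' @param x an object.
#' @return \code{networkNodes}: character vector of gene symbols;
#'   \code{networkEdges}/\code{networkMembers}: a data.frame;
#'   \code{seedGenes}/\code{memberGenes}: character vector;
#'   \code{subtypeOf}: character scalar.
#' @name accessors
#' @examples
#' net <- mergeNetworks(list(data.frame(source = "A", target = "B",
#'   directed = FALSE, provenance = "ppi")))
#' networkNodes(net)
#' networkEdges(net)
NULL

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname accessors
#' @export
setGeneric("networkMembers", function(x) standardGeneric("networkMembers"))

#' @rdname accessors
#' @export
setGeneric("memberGenes", function(x) standardGeneric("memberGenes"))

#' @rdname accessors
#' @export
setGeneric("subtypeOf", function(x) standardGeneric("subtypeOf"))

#' @rdname accessors
#' @export
setMethod("networkNodes", "NetworkSpace", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "NetworkSpace", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("seedGenes", "SeedSet", function(x) x@seeds$gene)

#' @rdname accessors
#' @export
setMethod("networkMembers", "DriverNetwork", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("memberGenes", "DriverNetwork", function(x) x@members$gene)

#' @rdname accessors
#' @export
setMethod("subtypeOf", "SeedSet", function(x) x@subtype)

#' @rdname accessors
#' @export
setMethod("subtypeOf", "DriverNetwork", function(x) x@subtype)

#' @rdname accessors
#' @export
setMethod("subtypeOf", "DifferentialExpressionResult", function(x) x@subtype)

setMethod("show", "NetworkSpace", function(object) {
  ed <- object@edges
  cat("NetworkSpace with", length(object@nodes), "genes and",
      nrow(ed), "edges\n")
  if (nrow(ed)) {
    tab <- table(ed$provenance)
    cat("  provenance:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "OmicsCohort", function(object) {
  shared <- intersect(colnames(object@expression), colnames(object@cna))
  cat("OmicsCohort:", nrow(object@expression), "probes x",
      ncol(object@expression), "samples (expression);",
      nrow(object@cna), "genes x", ncol(object@cna), "samples (CNA",
      if (object@cnaDiscrete) "calls)" else "log-ratios)", "\n")
  cat("  analysed samples (intersection):", length(shared), "\n")
  tab <- table(object@labels[shared])
  cat("  subtypes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet for subtype", object@subtype, "with",
      nrow(object@seeds), "seed genes\n")
  if (nrow(object@seeds))
    cat(" ", paste(utils::head(object@seeds$gene, 8), collapse = ", "),
        if (nrow(object@seeds) > 8) "...\n" else "\n")
})

setMethod("show", "DifferentialExpressionResult", function(object) {
  cat("DifferentialExpressionResult for subtype", object@subtype, ":",
      length(object@selectedProbes), "probes /",
      length(object@selectedGenes), "genes selected of",
      nrow(object@table), "probes\n")
})

setMethod("show", "DriverNetwork", function(object) {
  m <- object@members
  cat("DriverNetwork for subtype", object@subtype, "with",
      nrow(m), "members (", sum(m$is_seed), "seeds ) and",
      nrow(object@edges), "induced edges\n")
  if (nrow(m)) {
    tab <- table(m$inclusion_reason)
    cat("  reasons:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution (", object@scheme, "), ", object@reps,
      " reps: mean=", round(mean(object@overlaps), 3),
      " sd=", round(stats::sd(object@overlaps), 3), sep = "")
  if (!is.na(object@observed))
    cat(", observed=", round(object@observed, 3),
        ", p=", signif(object@pValue, 3), sep = "")
  cat("\n")
})
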