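#' Read an interactome edge list
#'
#' Parses a tab-separated edge list into a set of interaction edges with a
#' uniform provenance and directedness. Two dialects are accepted: plain
#' 2-column (\code{source<TAB>target}, an optional third column is ignored
#' unless it is a SIF relation) and SIF (\code{source<TAB>relation<TAB>target}
#' when \code{sif = TRUE}). Gene symbols are upper-cased on load; self-loops
#' are dropped (with a message) and duplicate edges are collapsed.
#'
#' @param path path to a tab-separated file.
#' @param provenance one of \code{"ppi"}, \code{"tf"}, \code{"signalling"}.
#' @param directed logical; \code{ppi} edges must be undirected, \code{tf}
#'   and \code{signalling} edges directed. Defaults to the conventional
#'   directedness of \code{provenance}.
#' @param sif logical, interpret the file as SIF
#'   (\code{source<TAB>relation<TAB>target}).
#' @param header logical, skip a header row.
#' @return data.frame of edges with columns \code{source}, \code{target},
#'   \code{directed}, \code{provenance}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tC", "C\tC"), tf)
#' readEdgeList(tf, provenance = "ppi")
#' @export
readEdgeList <- function(path, provenance = c("ppi", "tf", "signalling"),
                         directed = NULL, sif = FALSE, header = FALSE) {
  provenance <- match.arg(provenance)
  if (is.null(directed)) directed <- provenance != "ppi"
  stopifnot(is.logical(directed), length(directed) == 1L)
  if (provenance == "ppi" && directed)
    stop("ppi edges are undirected")
  if (provenance != "ppi" && !directed)
    stop(provenance, " edges are directed")
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (sif) 3L else 2L
  if (any(nf < minf))
    stop("malformed line ", which(nf < minf)[1L] + header, " in ", path,
         ": fewer than ", minf, " tab-separated fields")
  src <- toupper(vapply(fields, `[[`, "", 1L))
  tgt <- toupper(vapply(fields, `[[`, "", if (sif) 3L else 2L))
  edges <- data.frame(source = src, target = tgt,
                      directed = directed, provenance = provenance,
                      stringsAsFactors = FALSE)
  loops <- edges$source == edges$target
  if (any(loops))
    message("dropped ", sum(loops), " self-loop(s) from ", basename(path))
  edges <- edges[!loops, , drop = FALSE]
  edges <- edges[!duplicated(.edgeKey(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Merge edge lists into a combined network space
#'
#' Takes edge lists (as returned by [readEdgeList()], or data.frames with
#' the same columns) and merges them into a single [NetworkSpace-class]:
#' the node set is the union of all endpoint symbols and edges are
#' deduplicated per (pair, provenance), so an undirected \code{ppi} edge and
#' a directed \code{tf} edge between the same genes remain distinct edges.
#'
#' @param edgeLists a list of edge data.frames.
#' @param verbose report node and edge counts on load.
#' @return a [NetworkSpace-class].
#' @examples
#' ppi <- data.frame(source = "A", target = "B", directed = FALSE,
#'                   provenance = "ppi")
#' tf <- data.frame(source = "A", target = "B", directed = TRUE,
#'                  provenance = "tf")
#' mergeNetworks(list(ppi, tf))
#' @export
mergeNetworks <- function(edgeLists, verbose = FALSE) {
  stopifnot(is.list(edgeLists), length(edgeLists) >= 1L)
  ed <- do.call(rbind, lapply(edgeLists, function(e) {
    e <- as.data.frame(e)[, c("source", "target", "directed", "provenance")]
    e$source <- toupper(e$source); e$target <- toupper(e$target)
    e
  }))
  ed <- ed[ed$source != ed$target, , drop = FALSE]
  ed <- ed[!duplicated(.edgeKey(ed)), , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(c(ed$source, ed$target)))
  net <- new("NetworkSpace", edges = ed, nodes = nodes)
  if (verbose)
    message("network space: ", length(nodes), " genes, ", nrow(ed), " edges")
  net
}

#' Direct network neighbours of a gene
#'
#' Returns all genes adjacent to \code{gene} through any edge of the network
#' space. By default edges are traversed in both directions (directed
#' regulatory/signalling arrows are treated as adjacency, not as traversal
#' constraints); set \code{respectDirection = TRUE} to follow directed edges
#' only source-to-target.
#'
#' @param net a [NetworkSpace-class].
#' @param gene a gene symbol present in the network.
#' @param respectDirection logical, traverse directed edges downstream only.
#' @return character vector of neighbour gene symbols (never includes
#'   \code{gene} itself).
#' @examples
#' net <- mergeNetworks(list(
#'   data.frame(source = "A", target = "B", directed = FALSE,
#'              provenance = "ppi"),
#'   data.frame(source = "C", target = "A", directed = TRUE,
#'              provenance = "tf")))
#' neighborGenes(net, "A")
#' @export
neighborGenes <- function(net, gene, respectDirection = FALSE) {
  stopifnot(is(net, "NetworkSpace"))
  gene <- toupper(gene)
  if (!gene %in% net@nodes) stop("unknown gene: ", gene)
  ed <- net@edges
  out <- ed$target[ed$source == gene]
  if (respectDirection) {
    inc <- ed$source[ed$target == gene & !ed$directed]
  } else {
    inc <- ed$source[ed$target == gene]
  }
  sort(setdiff(unique(c(out, inc)), gene))
}

#' Export a network space to a tab-separated edge table
#'
#' Writes columns \code{source}, \code{target}, \code{directed},
#' \code{provenance}; [readNetworkSpace()] reloads the result losslessly.
#'
#' @param net a [NetworkSpace-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkSpace <- function(net, path) {
  stopifnot(is(net, "NetworkSpace"))
  utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network space written by [writeNetworkSpace()]
#'
#' @param path path to a 4-column tab-separated edge table.
#' @return a [NetworkSpace-class].
#' @export
readNetworkSpace <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  ed$directed <- as.logical(ed$directed)
  mergeNetworks(list(ed))
}

#' Connected components of the subgraph induced by a gene set
#'
#' Used to distinguish the main driver-network component from satellite
#' subnetworks. Direction is ignored.
#'
#' @param net a [NetworkSpace-class].
#' @param genes gene symbols; genes absent from the network form singleton
#'   components.
#' @return integer vector of component ids named by gene, numbered by
#'   decreasing component size (1 = main component).
#' @export
networkComponents <- function(net, genes) {
  stopifnot(is(net, "NetworkSpace"))
  genes <- unique(toupper(genes))
  ed <- net@edges
  keep <- ed$source %in% genes & ed$target %in% genes
  g <- igraph::graph_from_data_frame(
    ed[keep, c("source", "target"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  rk <- stats::setNames(rank(-as.integer(sizes), ties.method = "first"),
                        names(sizes))
  out <- as.integer(rk[as.character(comp)])
  names(out) <- names(comp)
  out[genes]
}
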