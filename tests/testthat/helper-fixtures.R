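# Fixture builders and independent oracles used across the suite.

# small network from a compact edge spec: "A-B" undirected ppi, "A>B" tf
tinyNet <- function(...) {
  specs <- c(...)
  rows <- lapply(specs, function(s) {
    if (grepl(">", s, fixed = TRUE)) {
      p <- strsplit(s, ">", fixed = TRUE)[[1]]
      data.frame(source = p[1], target = p[2], directed = TRUE,
                 provenance = "tf", stringsAsFactors = FALSE)
    } else {
      p <- strsplit(s, "-", fixed = TRUE)[[1]]
      data.frame(source = p[1], target = p[2], directed = FALSE,
                 provenance = "ppi", stringsAsFactors = FALSE)
    }
  })
  mergeNetworks(rows)
}

# cohort with one probe per gene from explicit matrices
makeCohort <- function(expr, cna = NULL, labels) {
  genes <- rownames(expr)
  probeMap <- stats::setNames(genes, paste0(genes, "_p"))
  rownames(expr) <- names(probeMap)
  if (is.null(cna)) {
    cna <- matrix(0, length(genes), ncol(expr),
                  dimnames = list(genes, colnames(expr)))
  }
  suppressMessages(OmicsCohort(expr, probeMap, cna, labels))
}

# deterministic sample labels s1..sn split into two groups
twoGroups <- function(nIn, nOut, subtype = "T", rest = "R") {
  stats::setNames(factor(rep(c(subtype, rest), c(nIn, nOut))),
                  paste0("s", seq_len(nIn + nOut)))
}

# Brute-force fixed-point oracle for driver-network expansion: rescan every
# (member, neighbour) pair until closure. Independent of the package's BFS.
oracleExpand <- function(edges, seeds, deGenes, qualEdges) {
  qualKey <- paste(pmin(qualEdges$a, qualEdges$b),
                   pmax(qualEdges$a, qualEdges$b))
  members <- unique(seeds)
  repeat {
    added <- FALSE
    for (m in members) {
      nb <- unique(c(edges$target[edges$source == m],
                     edges$source[edges$target == m]))
      for (v in setdiff(nb, members)) {
        ok <- v %in% deGenes ||
          (m %in% deGenes &&
           paste(min(m, v), max(m, v)) %in% qualKey)
        if (ok) {
          members <- c(members, v)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  sort(members)
}

# closed-form Welch oracle via stats::t.test, one probe at a time
oracleWelchP <- function(X, grp, pooled = FALSE) {
  apply(X, 1L, function(v) {
    stats::t.test(v[grp], v[!grp], var.equal = pooled)$p.value
  })
}
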