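#' Generator configuration for synthetic cohorts
#'
#' Default settings describe the benchmark condition used throughout the
#' package: a 2000-gene interactome (mean degree 4), three subtypes with
#' 20/10/30 samples, a planted 4-seed module of radius 1 hop in the
#' 30-sample target subtype, near-certain seed amplification (0.9) against
#' a 5% background alteration rate, an expression effect of 2 noise SDs and
#' within-subtype co-expression of 0.8 on module edges. A null cohort (no
#' planted signal) is obtained with \code{expressionEffect = 0},
#' \code{coexpressionStrength = 0} and \code{cnaGainProbInTarget} equal to
#' the background gain rate.
#'
#' @param nGenes number of genes in the synthetic interactome.
#' @param meanDegree target mean degree of the preferential-attachment
#'   graph.
#' @param nSamples named integer vector: samples per subtype.
#' @param targetSubtype the subtype carrying the planted module.
#' @param seedGenes number of planted seed (amplified driver) genes.
#' @param moduleRadius module extent in hops around the planted seeds.
#' @param cnaGainProbInTarget per-sample gain probability of planted seeds
#'   in target-subtype samples.
#' @param backgroundGainProb,backgroundLossProb per-gene-per-sample
#'   background alteration probabilities (all genes, all subtypes).
#' @param expressionEffect expression shift in units of \code{noiseSd}
#'   applied to non-seed module genes in target samples (the differential
#'   overexpression signal).
#' @param seedCouplingEffect expression shift per CNA call unit for planted
#'   seeds (the dosage coupling that the seed filter looks for); defaults
#'   to \code{expressionEffect}. Lower values give seeds that are
#'   dosage-coupled but not themselves differentially expressed.
#' @param coexpressionStrength target within-subtype Pearson correlation of
#'   planted module edges, in [0, 1).
#' @param noiseSd expression noise standard deviation (log-scale units).
#' @param multiProbeFrac fraction of genes emitted with a second probe.
#' @param rngSeed integer seed.
#' @return list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nGenes = 2000L, meanDegree = 4,
                            nSamples = c(ERpos = 20L, HER2pos = 10L,
                                         TNBC = 30L),
                            targetSubtype = "TNBC",
                            seedGenes = 4L, moduleRadius = 1L,
                            cnaGainProbInTarget = 0.9,
                            backgroundGainProb = 0.025,
                            backgroundLossProb = 0.025,
                            expressionEffect = 2,
                            seedCouplingEffect = expressionEffect,
                            coexpressionStrength = 0.8,
                            noiseSd = 1, multiProbeFrac = 0.1,
                            rngSeed = 1L) {
  stopifnot(nGenes >= 10L, seedGenes >= 1L, moduleRadius >= 0L,
            cnaGainProbInTarget >= 0, cnaGainProbInTarget <= 1,
            backgroundGainProb >= 0, backgroundGainProb <= 1,
            backgroundLossProb >= 0, backgroundLossProb <= 1,
            expressionEffect >= 0, seedCouplingEffect >= 0,
            coexpressionStrength >= 0,
            coexpressionStrength < 1, noiseSd > 0,
            targetSubtype %in% names(nSamples))
  structure(list(nGenes = as.integer(nGenes), meanDegree = meanDegree,
                 nSamples = nSamples, targetSubtype = targetSubtype,
                 seedGenes = as.integer(seedGenes),
                 moduleRadius = as.integer(moduleRadius),
                 cnaGainProbInTarget = cnaGainProbInTarget,
                 backgroundGainProb = backgroundGainProb,
                 backgroundLossProb = backgroundLossProb,
                 expressionEffect = expressionEffect,
                 seedCouplingEffect = seedCouplingEffect,
                 coexpressionStrength = coexpressionStrength,
                 noiseSd = noiseSd, multiProbeFrac = multiProbeFrac,
                 rngSeed = as.integer(rngSeed)),
            class = "GeneratorConfig")
}

#' Generate a synthetic interactome
#'
#' A preferential-attachment (heavy-tailed degree distribution) random
#' graph over \code{nGenes} gene symbols; a random subset of edges is
#' marked as directed transcription-regulatory or signalling interactions,
#' the rest as undirected protein-protein interactions.
#'
#' @param nGenes number of genes (>= 10).
#' @param meanDegree target mean degree (edges ~ nGenes * meanDegree / 2).
#' @param rngSeed integer seed; identical seeds give identical graphs.
#' @param tfFrac,signallingFrac fractions of edges assigned to the directed
#'   provenances.
#' @return a [NetworkSpace-class].
#' @export
generateNetwork <- function(nGenes, meanDegree = 4, rngSeed = 1L,
                            tfFrac = 0.2, signallingFrac = 0.1) {
  stopifnot(nGenes >= 10L)
  set.seed(rngSeed)
  g <- igraph::sample_pa(nGenes, power = 1,
                         m = max(1L, round(meanDegree / 2)),
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  gene <- sprintf("G%05d", seq_len(nGenes))
  nE <- nrow(el)
  prov <- sample(c("ppi", "tf", "signalling"), nE, replace = TRUE,
                 prob = c(1 - tfFrac - signallingFrac, tfFrac,
                          signallingFrac))
  flip <- sample(c(TRUE, FALSE), nE, replace = TRUE)
  src <- ifelse(flip, el[, 1L], el[, 2L])
  tgt <- ifelse(flip, el[, 2L], el[, 1L])
  mergeNetworks(list(data.frame(source = gene[src], target = gene[tgt],
                                directed = prov != "ppi",
                                provenance = prov,
                                stringsAsFactors = FALSE)))
}

.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    networkEdges(net)[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = networkNodes(net)))
}

#' Plant a driver-module truth in a network
#'
#' Chooses \code{cfg$seedGenes} planted seed genes among moderate-degree
#' nodes (degree 2-6 where possible, emulating amplicons hitting typical
#' genes rather than hubs) and defines the planted module as all genes
#' within \code{cfg$moduleRadius} hops of a seed; planted co-expression
#' edges are the network edges internal to the module.
#'
#' @param net a [NetworkSpace-class].
#' @param cfg a [generatorConfig()].
#' @return list of class \code{"SyntheticTruth"}: \code{seeds},
#'   \code{module} (gene symbols, seeds included), \code{coexprEdges}
#'   (two-column matrix; a maximal matching of the module-internal edges,
#'   so each gene carries at most one latent factor and the within-subtype
#'   correlation of a planted edge stays at its calibrated value).
#' @export
plantTruth <- function(net, cfg) {
  set.seed(cfg$rngSeed)
  g <- .asIgraph(net)
  deg <- igraph::degree(g)
  # amplicons hit typical genes, not hubs: cap candidate degree at the
  # larger of 6 and the median degree
  cap <- max(6, stats::median(deg))
  cand <- names(deg)[deg >= 2 & deg <= cap]
  if (length(cand) < cfg$seedGenes) cand <- names(deg)[deg >= 1]
  seeds <- sample(cand, cfg$seedGenes)
  module <- seeds
  frontier <- seeds
  for (h in seq_len(cfg$moduleRadius)) {
    nbList <- igraph::adjacent_vertices(g, frontier)
    nb <- unique(unlist(lapply(nbList, function(v) names(v)),
                        use.names = FALSE))
    new <- setdiff(nb, module)
    if (!length(new)) {
      warning("module truncated: no new genes at hop ", h)
      break
    }
    module <- c(module, new)
    frontier <- new
  }
  ed <- networkEdges(net)
  keep <- ed$source %in% module & ed$target %in% module
  inner <- unique(cbind(pmin(ed$source[keep], ed$target[keep]),
                        pmax(ed$source[keep], ed$target[keep])))
  # greedy maximal matching: one shared factor per gene keeps the
  # within-subtype correlation of a planted edge at its calibrated value
  used <- character(0)
  pick <- logical(nrow(inner))
  for (e in seq_len(nrow(inner))) {
    if (inner[e, 1L] %in% used || inner[e, 2L] %in% used) next
    pick[e] <- TRUE
    used <- c(used, inner[e, ])
  }
  coexprEdges <- inner[pick, , drop = FALSE]
  structure(list(seeds = seeds, module = module,
                 coexprEdges = coexprEdges),
            class = "SyntheticTruth")
}

#' Generate a synthetic omics cohort with a planted driver module
#'
#' Builds paired copy-number and expression data over the genes of a
#' synthetic interactome. Copy number: planted seeds gain (log-ratio well
#' above the 0.3 gain threshold) with probability
#' \code{cfg$cnaGainProbInTarget} in target-subtype samples; all genes gain
#' or lose at the background rates elsewhere. Expression: per-probe
#' Gaussian noise; planted seeds additionally follow their CNA calls
#' (dosage coupling of \code{expressionEffect} per call unit, inducing the
#' CNA-expression correlation the seed filter looks for); non-seed module
#' genes are shifted by \code{expressionEffect} in target samples (inducing
#' differential overexpression); each planted module edge shares a latent
#' factor in target samples only, calibrated so the within-subtype Pearson
#' correlation of an isolated module edge is about
#' \code{coexpressionStrength} (inducing differential co-expression). A
#' fraction of genes is emitted with two probes.
#'
#' Two independent cohorts for reproducibility experiments share a truth:
#' call with the same \code{truth} and different \code{cohortSeed}.
#'
#' @param net a [NetworkSpace-class].
#' @param cfg a [generatorConfig()].
#' @param truth optional [plantTruth()] result to reuse; planted from
#'   \code{cfg} when NULL.
#' @param cohortSeed RNG seed for this cohort's noise and events (defaults
#'   to \code{cfg$rngSeed}).
#' @return list: \code{cohort} ([OmicsCohort-class]), \code{truth}.
#' @export
generateCohort <- function(net, cfg, truth = NULL,
                           cohortSeed = cfg$rngSeed) {
  genes <- networkNodes(net)
  if (is.null(truth)) truth <- plantTruth(net, cfg)
  stopifnot(all(truth$seeds %in% genes))
  set.seed(cohortSeed)
  nS <- sum(cfg$nSamples)
  samples <- sprintf("S%03d", seq_len(nS))
  labels <- stats::setNames(
    factor(rep(names(cfg$nSamples), cfg$nSamples)), samples)
  target <- as.character(labels) == cfg$targetSubtype
  G <- length(genes)

  # copy number: continuous log-ratios with discrete-valued events
  gainP <- matrix(cfg$backgroundGainProb, G, nS,
                  dimnames = list(genes, samples))
  lossP <- matrix(cfg$backgroundLossProb, G, nS,
                  dimnames = list(genes, samples))
  gainP[truth$seeds, target] <- cfg$cnaGainProbInTarget
  lossP[truth$seeds, target] <- 0
  u <- matrix(stats::runif(G * nS), G, nS)
  isGain <- u < gainP
  isLoss <- !isGain & u < gainP + lossP
  cna <- matrix(stats::rnorm(G * nS, 0, 0.05), G, nS,
                dimnames = list(genes, samples))
  cna[isGain] <- 0.8 + stats::rnorm(sum(isGain), 0, 0.1)
  cna[isLoss] <- -0.8 + stats::rnorm(sum(isLoss), 0, 0.1)
  calls <- discretizeCNA(cna)

  # per-gene expression signal
  signal <- matrix(0, G, nS, dimnames = list(genes, samples))
  signal[truth$seeds, ] <- cfg$seedCouplingEffect * cfg$noiseSd *
    calls[truth$seeds, ]
  others <- setdiff(truth$module, truth$seeds)
  if (length(others))
    signal[others, target] <- signal[others, target] +
      cfg$expressionEffect * cfg$noiseSd
  rho <- cfg$coexpressionStrength
  if (rho > 0 && nrow(truth$coexprEdges)) {
    loading <- cfg$noiseSd * sqrt(rho / (1 - rho))
    nT <- sum(target)
    for (e in seq_len(nrow(truth$coexprEdges))) {
      f <- stats::rnorm(nT) * loading
      signal[truth$coexprEdges[e, 1L], target] <-
        signal[truth$coexprEdges[e, 1L], target] + f
      signal[truth$coexprEdges[e, 2L], target] <-
        signal[truth$coexprEdges[e, 2L], target] + f
    }
  }

  # probes: every gene gets one, a fraction a second (noisier) one
  second <- genes[stats::runif(G) < cfg$multiProbeFrac]
  probeGenes <- c(genes, second)
  probeIds <- c(paste0(genes, "_p1"),
                if (length(second)) paste0(second, "_p2"))
  expr <- signal[probeGenes, , drop = FALSE] +
    matrix(stats::rnorm(length(probeGenes) * nS, 0, cfg$noiseSd),
           length(probeGenes), nS)
  rownames(expr) <- probeIds
  probeMap <- stats::setNames(probeGenes, probeIds)
  cohort <- suppressMessages(
    OmicsCohort(expr, probeMap, cna, labels, cnaDiscrete = FALSE))
  list(cohort = cohort, truth = truth)
}

#' Generate a synthetic siRNA viability screen
#'
#' Emulates the validation screen layout: each gene x cell line is measured
#' with \code{nSirnas} siRNAs of \code{nReplicates} replicates; viability
#' is \code{1 - effect + noise} truncated at 0, with the effect set by the
#' cell line's group; control measurements per cell line are
#' \code{1 + noise}.
#'
#' @param genes character vector of genes screened.
#' @param effectTarget,effectOther mean viability reduction in
#'   target-subtype and other cell lines.
#' @param nTargetLines,nOtherLines cell lines per group.
#' @param nSirnas,nReplicates screen layout (defaults 4 x 3).
#' @param nControlReplicates control measurements per cell line.
#' @param noiseSd measurement noise SD.
#' @param rngSeed integer seed.
#' @return screen data.frame (see [readScreen()]).
#' @export
generateScreen <- function(genes, effectTarget = 0.5, effectOther = 0.1,
                           nTargetLines = 9L, nOtherLines = 4L,
                           nSirnas = 4L, nReplicates = 3L,
                           nControlReplicates = 12L, noiseSd = 0.1,
                           rngSeed = 1L) {
  stopifnot(effectTarget >= 0, effectOther >= 0, length(genes) >= 1L)
  set.seed(rngSeed)
  lines <- data.frame(
    cell_line = c(sprintf("TLINE%02d", seq_len(nTargetLines)),
                  sprintf("OLINE%02d", seq_len(nOtherLines))),
    group = rep(c("target_subtype", "other"),
                c(nTargetLines, nOtherLines)),
    effect = rep(c(effectTarget, effectOther),
                 c(nTargetLines, nOtherLines)))
  out <- list()
  for (i in seq_len(nrow(lines))) {
    cl <- lines$cell_line[i]
    out[[length(out) + 1L]] <- data.frame(
      gene = "CONTROL", sirna_id = "ctrl", cell_line = cl,
      group = lines$group[i],
      replicate = seq_len(nControlReplicates),
      viability = pmax(0, 1 + stats::rnorm(nControlReplicates, 0,
                                           noiseSd)),
      is_control = TRUE, stringsAsFactors = FALSE)
    for (g in genes) for (s in seq_len(nSirnas)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, sirna_id = paste0(g, "_si", s), cell_line = cl,
        group = lines$group[i], replicate = seq_len(nReplicates),
        viability = pmax(0, 1 - lines$effect[i] +
                         stats::rnorm(nReplicates, 0, noiseSd)),
        is_control = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a complete simulation to disk
#'
#' Writes the network (\code{network.tsv}), the cohort tables (see
#' [writeCohort()]) and the planted truth (\code{truth_genes.tsv},
#' \code{truth_edges.tsv}) into a directory.
#'
#' @param dir output directory.
#' @param net a [NetworkSpace-class].
#' @param cohort an [OmicsCohort-class].
#' @param truth a [plantTruth()] result.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(dir, net, cohort, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNetworkSpace(net, file.path(dir, "network.tsv"))
  writeCohort(cohort, dir)
  utils::write.table(
    data.frame(gene = truth$module,
               is_seed = truth$module %in% truth$seeds),
    file.path(dir, "truth_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(geneA = truth$coexprEdges[, 1L],
               geneB = truth$coexprEdges[, 2L]),
    file.path(dir, "truth_edges.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
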