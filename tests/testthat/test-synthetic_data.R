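test_that("generated networks are deterministic with the expected density", {
  n1 <- generateNetwork(100, 4, rngSeed = 8)
  n2 <- generateNetwork(100, 4, rngSeed = 8)
  expect_identical(networkEdges(n1), networkEdges(n2))
  expect_equal(length(networkNodes(n1)), 100L)
  e <- nrow(networkEdges(n1))
  expect_true(e >= 150 && e <= 250)          # ~ n * meanDegree / 2
  expect_true(all(networkEdges(n1)$provenance %in%
                  c("ppi", "tf", "signalling")))
})

test_that("preferential attachment gives heavier degree tails than G(n, m)", {
  maxPA <- maxER <- numeric(10)
  for (i in 1:10) {
    pa <- generateNetwork(300, 4, rngSeed = i)
    degPA <- table(c(networkEdges(pa)$source, networkEdges(pa)$target))
    set.seed(i)
    er <- igraph::sample_gnm(300, nrow(networkEdges(pa)))
    maxPA[i] <- max(degPA)
    maxER[i] <- max(igraph::degree(er))
  }
  expect_gt(mean(maxPA), mean(maxER))
})

test_that("planted truth is internally consistent", {
  net <- generateNetwork(300, 4, rngSeed = 9)
  cfg <- generatorConfig(nGenes = 300, seedGenes = 4L, rngSeed = 9)
  truth <- plantTruth(net, cfg)
  expect_true(all(truth$seeds %in% truth$module))
  expect_true(all(truth$module %in% networkNodes(net)))
  # planted co-expression edges are network edges internal to the module,
  # and form a matching (no gene carries two latent factors)
  expect_true(all(truth$coexprEdges %in% truth$module))
  expect_false(anyDuplicated(as.vector(truth$coexprEdges)) > 0)
  # radius-1 module genes are seeds or their direct neighbours
  nonseed <- setdiff(truth$module, truth$seeds)
  nbAll <- unique(unlist(lapply(truth$seeds, neighborGenes, net = net)))
  expect_true(all(nonseed %in% nbAll))
})

test_that("cohorts are reproducible and reflect the planted mechanisms", {
  net <- generateNetwork(300, 4, rngSeed = 10)
  cfg <- generatorConfig(nGenes = 300, nSamples = c(A = 10L, B = 5L, C = 15L),
                         targetSubtype = "C", seedGenes = 3L,
                         cnaGainProbInTarget = 1, rngSeed = 10)
  s1 <- generateCohort(net, cfg)
  s2 <- generateCohort(net, cfg)
  expect_identical(s1$cohort@expression, s2$cohort@expression)

  # certain amplification: seed average CNA score is exactly 1 in target
  disc <- discretizeCNA(s1$cohort@cna)
  sc <- averageCNAScore(disc, s1$cohort@labels, "C")
  expect_equal(unname(sc[s1$truth$seeds]), rep(1, 3))

  # dosage coupling raises the seeds' pooled CNA-expression correlation
  r <- suppressMessages(cnaExprCorrelation(s1$cohort))
  expect_true(all(r[s1$truth$seeds] > 0.3))

  # planted co-expression edges correlate within the target subtype only
  if (nrow(s1$truth$coexprEdges)) {
    e <- s1$truth$coexprEdges[1, ]
    d <- edgeDifferentialCorrelation(e[1], e[2], s1$cohort, "C")
    expect_gt(d$delta, 0.3)
  }
})

test_that("planted seeds pass both seed filters in most generator draws", {
  hits <- total <- 0
  for (g in 1:20) {
    net <- generateNetwork(2000, 4, rngSeed = g + 40)
    cfg <- generatorConfig(rngSeed = g + 40)
    sim <- generateCohort(net, cfg)
    ss <- suppressWarnings(selectSeedsFromCohort(sim$cohort, "TNBC"))
    hits <- hits + sum(sim$truth$seeds %in% seedGenes(ss))
    total <- total + length(sim$truth$seeds)
  }
  expect_gte(hits / total, 0.9)
})

test_that("a null generator leaves planted seeds at chance-level selection", {
  set.seed(60)
  inSet <- expected <- 0
  for (g in 1:15) {
    net <- generateNetwork(500, 4, rngSeed = g + 60)
    cfg <- generatorConfig(nGenes = 500, seedGenes = 4L,
                           nSamples = c(A = 10L, B = 10L, C = 10L),
                           targetSubtype = "B", expressionEffect = 0,
                           coexpressionStrength = 0,
                           cnaGainProbInTarget = 0.025, rngSeed = g + 60)
    sim <- generateCohort(net, cfg)
    ss <- suppressWarnings(selectSeedsFromCohort(sim$cohort, "B"))
    universe <- suppressMessages(length(cnaExprCorrelation(sim$cohort)))
    inSet <- inSet + sum(sim$truth$seeds %in% seedGenes(ss))
    expected <- expected + 4 * length(seedGenes(ss)) / universe
  }
  # planted seeds selected no more often than chance (binomial slack)
  expect_lte(inSet, expected + 3 * sqrt(expected))
})

test_that("generated screens are deterministic with the stated layout", {
  s1 <- generateScreen(c("G1", "G2"), rngSeed = 61)
  s2 <- generateScreen(c("G1", "G2"), rngSeed = 61)
  expect_identical(s1, s2)
  g1 <- s1[!s1$is_control & s1$gene == "G1" & s1$cell_line == "TLINE01", ]
  expect_equal(length(unique(g1$sirna_id)), 4L)     # 4 siRNAs
  expect_equal(nrow(g1), 12L)                       # x 3 replicates
  expect_equal(length(unique(s1$cell_line)), 13L)
  expect_true(all(s1$viability >= 0))
})

test_that("simulations written to disk reload through the package readers", {
  net <- generateNetwork(60, 4, rngSeed = 62)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 60, nSamples = c(A = 5L, B = 5L, C = 5L), targetSubtype = "B",
    seedGenes = 2L, rngSeed = 62))
  d <- withr::local_tempdir()
  writeSimulation(d, net, sim$cohort, sim$truth)
  net2 <- readNetworkSpace(file.path(d, "network.tsv"))
  expect_setequal(networkNodes(net2), networkNodes(net))
  co <- readCohort(d)
  expect_equal(co@expression, sim$cohort@expression, tolerance = 1e-9)
  tg <- read.delim(file.path(d, "truth_genes.tsv"))
  expect_setequal(tg$gene, sim$truth$module)
  expect_setequal(tg$gene[tg$is_seed], sim$truth$seeds)
})
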