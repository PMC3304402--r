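# builds a DifferentialExpressionResult carrying an explicit gene set
fakeDE <- function(genes, subtype = "T") {
  new("DifferentialExpressionResult", subtype = subtype,
      table = data.frame(), selectedProbes = character(0),
      selectedGenes = toupper(genes), thresholds = numeric(0))
}

# minimal cohort over the network's genes with iid noise expression
noiseCohort <- function(net, nIn = 6, nOut = 6, seed = 1) {
  set.seed(seed)
  lab <- twoGroups(nIn, nOut)
  genes <- networkNodes(net)
  expr <- matrix(rnorm(length(genes) * (nIn + nOut)), length(genes),
                 dimnames = list(genes, names(lab)))
  makeCohort(expr, labels = lab)
}

test_that("differentially expressed neighbours chain out from the seed", {
  net <- tinyNet("S-N1", "N1-N3", "S-N2")
  co <- noiseCohort(net)
  dn <- expandDriverNetwork("S", net, co, "T",
                            de = fakeDE(c("N1", "N3")),
                            deltaThreshold = Inf)
  expect_setequal(memberGenes(dn), c("S", "N1", "N3"))
  m <- networkMembers(dn)
  expect_equal(m$inclusion_reason[m$gene == "N1"], "differential_expression")
  expect_equal(m$inclusion_reason[m$gene == "S"], "seed")
  expect_true(all(m$membership_frequency == 1))
})

test_that("co-expression only counts from differentially expressed members", {
  net <- tinyNet("S-N1")
  co <- noiseCohort(net)
  # seed not DE: the qualifying edge is ignored, network stays at the seed
  dn <- expandDriverNetwork("S", net, co, "T", de = fakeDE(character(0)),
                            deltaThreshold = -Inf)
  expect_setequal(memberGenes(dn), "S")
  # once the seed is DE the same edge admits its partner
  dn2 <- expandDriverNetwork("S", net, co, "T", de = fakeDE("S"),
                             deltaThreshold = -Inf)
  expect_setequal(memberGenes(dn2), c("S", "N1"))
  m <- networkMembers(dn2)
  expect_equal(m$inclusion_reason[m$gene == "N1"], "coexpression_only")
  expect_equal(m$inclusion_reason[m$gene == "S"],
               "seed+differential_expression")
})

test_that("seeds absent from the network are kept as isolated members", {
  net <- tinyNet("A-B")
  co <- noiseCohort(net)
  expect_warning(
    dn <- expandDriverNetwork(c("A", "ZZZ"), net, co, "T",
                              de = fakeDE(character(0)),
                              deltaThreshold = Inf),
    "isolated")
  expect_setequal(memberGenes(dn), c("A", "ZZZ"))
})

test_that("expansion equals the exhaustive fixed-point oracle on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(10:50, 1)
    net <- generateNetwork(n, 4, rngSeed = rep)
    co <- noiseCohort(net, seed = rep + 100)
    genes <- networkNodes(net)
    seeds <- sample(genes, sample(1:3, 1))
    deGenes <- sample(genes, min(length(genes) - 1L, rnbinom(1, 5, 0.4)))
    # random qualifying edge subset via a random delta threshold quantile
    tab <- edgeDeltaTable(net, co, "T")
    thr <- stats::quantile(tab$delta, runif(1, 0.5, 1))
    dn <- expandDriverNetwork(seeds, net, co, "T", de = fakeDE(deGenes),
                              deltaThreshold = thr)
    qual <- tab[tab$delta >= thr, , drop = FALSE]
    want <- oracleExpand(networkEdges(net), seeds, deGenes,
                         data.frame(a = qual$geneA, b = qual$geneB))
    expect_setequal(memberGenes(dn), want)
  }
})

test_that("the fixed point does not depend on edge or seed ordering", {
  net <- generateNetwork(40, 6, rngSeed = 32)
  co <- noiseCohort(net, seed = 32)
  genes <- networkNodes(net)
  de <- fakeDE(sample(genes, 8))
  seeds <- sample(genes, 3)
  ref <- memberGenes(expandDriverNetwork(seeds, net, co, "T", de = de,
                                         deltaThreshold = 0.5))
  for (i in 1:3) {
    ed <- networkEdges(net)[sample(nrow(networkEdges(net))), ]
    net2 <- mergeNetworks(list(ed))
    got <- memberGenes(expandDriverNetwork(rev(seeds), net2, co, "T",
                                           de = de, deltaThreshold = 0.5))
    expect_setequal(got, ref)
  }
})

test_that("enlarging the DE set never shrinks the member set", {
  net <- generateNetwork(40, 4, rngSeed = 33)
  co <- noiseCohort(net, seed = 33)
  genes <- networkNodes(net)
  seeds <- genes[1:2]
  de1 <- sample(genes, 6)
  m1 <- memberGenes(expandDriverNetwork(seeds, net, co, "T",
                                        de = fakeDE(de1),
                                        deltaThreshold = 0.4))
  m2 <- memberGenes(expandDriverNetwork(seeds, net, co, "T",
                                        de = fakeDE(c(de1, genes[30])),
                                        deltaThreshold = 0.4))
  expect_true(all(m1 %in% m2))
})

test_that("co-expression members always have a qualifying edge to a DE member", {
  net <- generateNetwork(200, 6, rngSeed = 34)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 200, meanDegree = 6, nSamples = c(A = 10L, B = 10L, C = 10L),
    targetSubtype = "B", seedGenes = 3L, rngSeed = 34))
  dn <- expandDriverNetwork(seedSet(sim$truth$seeds, "B"), net, sim$cohort)
  m <- networkMembers(dn)
  de <- differentialExpression(sim$cohort, "B")@selectedGenes
  for (g in m$gene[m$inclusion_reason == "coexpression_only"]) {
    ed <- dn@edges
    inc <- ed[(ed$source == g | ed$target == g) & !is.na(ed$delta) &
              ed$delta >= dn@deltaThreshold, , drop = FALSE]
    other <- ifelse(inc$source == g, inc$target, inc$source)
    expect_true(any(other %in% de & other %in% m$gene))
  }
})

test_that("resampling is deterministic and honours the frequency filter", {
  net <- generateNetwork(150, 4, rngSeed = 35)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 150, nSamples = c(A = 10L, B = 10L, C = 10L),
    targetSubtype = "B", seedGenes = 2L, rngSeed = 35))
  sv <- seedSet(sim$truth$seeds, "B")
  r1 <- resampledDriverNetwork(sv, net, sim$cohort, reps = 20, rngSeed = 9)
  r2 <- resampledDriverNetwork(sv, net, sim$cohort, reps = 20, rngSeed = 9)
  expect_identical(attr(r1, "frequencies"), attr(r2, "frequencies"))
  m <- networkMembers(r1)
  expect_true(all(m$membership_frequency[!m$is_seed] >= 0.5))
  f <- attr(r1, "frequencies")
  dropped <- setdiff(names(f)[f > 0 & f < 0.5], seedGenes(sv))
  expect_false(any(dropped %in% memberGenes(r1)))
  expect_true(all(seedGenes(sv) %in% memberGenes(r1)))
})

test_that("sampleFrac = 1 reproduces the single-run network exactly", {
  net <- generateNetwork(150, 4, rngSeed = 36)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 150, nSamples = c(A = 10L, B = 10L, C = 10L),
    targetSubtype = "B", seedGenes = 2L, rngSeed = 36))
  sv <- seedSet(sim$truth$seeds, "B")
  single <- expandDriverNetwork(sv, net, sim$cohort)
  degen <- resampledDriverNetwork(sv, net, sim$cohort, sampleFrac = 1,
                                  reps = 5, rngSeed = 1)
  expect_setequal(memberGenes(degen), memberGenes(single))
  expect_true(all(networkMembers(degen)$membership_frequency == 1))
})

test_that("driver-network tables export and reload cleanly", {
  net <- generateNetwork(100, 4, rngSeed = 37)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 100, nSamples = c(A = 8L, B = 8L, C = 8L),
    targetSubtype = "B", seedGenes = 2L, rngSeed = 37))
  dn <- expandDriverNetwork(seedSet(sim$truth$seeds, "B"), net, sim$cohort)
  pre <- file.path(withr::local_tempdir(), "run")
  paths <- writeDriverNetwork(dn, pre)
  nodes <- read.delim(paths[1])
  expect_setequal(nodes$gene, memberGenes(dn))
  expect_true(all(c("inclusion_reason", "membership_frequency",
                    "is_seed") %in% names(nodes)))
})
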