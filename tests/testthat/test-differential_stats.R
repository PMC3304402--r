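test_that("degenerate probes get p = 1 and extreme separations are selected", {
  set.seed(21)
  lab <- twoGroups(5, 5)
  expr <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(paste0("p", 1:100), names(lab)))
  expr[1, ] <- rep(c(10, 0), each = 5) + rnorm(10, 0, 1e-3)  # extreme probe
  expr[2, ] <- 7                                             # constant probe
  co <- makeCohort(expr, labels = lab)
  de <- differentialExpression(co, "T")
  tab <- de@table
  expect_equal(tab$p_value[2], 1)                # zero variance both groups
  expect_equal(tab$selected_by[1], "both")       # lowest p and top median
  expect_true("P1" %in% de@selectedGenes)
  expect_error(differentialExpression(co, "nosuch"), ">= 2 samples")
})

test_that("Welch and pooled p-values match the t.test oracle everywhere", {
  set.seed(22)
  lab <- twoGroups(20, 40)
  grp <- as.character(lab) == "T"
  expr <- matrix(rnorm(1000 * 60), 1000, 60,
                 dimnames = list(paste0("p", 1:1000), names(lab)))
  co <- makeCohort(expr, labels = lab)
  for (variant in c("welch", "pooled")) {
    de <- differentialExpression(co, "T", variant = variant)
    oracle <- oracleWelchP(expr, grp, pooled = variant == "pooled")
    expect_lt(max(abs(de@table$p_value - oracle)), 1e-10)
  }
})

test_that("planted overexpressed probes are recovered by the rank rules", {
  set.seed(23)
  lab <- twoGroups(20, 40)
  expr <- matrix(rnorm(1000 * 60), 1000, 60,
                 dimnames = list(paste0("p", 1:1000), names(lab)))
  planted <- paste0("p", 1:20)
  expr[planted, as.character(lab) == "T"] <-
    expr[planted, as.character(lab) == "T"] + 3     # 3 SD effect
  co <- makeCohort(expr, labels = lab)
  de <- differentialExpression(co, "T")
  expect_gte(sum(toupper(planted) %in% de@selectedGenes), 18)
  # selection fractions honoured up to boundary ties
  tab <- de@table
  expect_lte(sum(tab$selected_by %in% c("p", "both")),
             ceiling(0.02 * 1000) + sum(tab$p_value == de@thresholds["p_cutoff"]))
  # only overexpression can be selected
  expect_true(all(tab$median_diff[tab$selected_by != "none"] > 0))
})

test_that("underexpressed probes are never selected despite small p-values", {
  set.seed(24)
  lab <- twoGroups(10, 10)
  expr <- matrix(rnorm(200 * 20), 200, 20,
                 dimnames = list(paste0("p", 1:200), names(lab)))
  expr[1, as.character(lab) == "T"] <- expr[1, as.character(lab) == "T"] - 5
  co <- makeCohort(expr, labels = lab)
  de <- differentialExpression(co, "T")
  tab <- de@table
  expect_lt(tab$p_value[1], 1e-6)
  expect_equal(tab$selected_by[1], "none")
})

test_that("edge differential correlation equals the covariance-formula oracle", {
  set.seed(25)
  lab <- twoGroups(5, 5)
  grp <- as.character(lab) == "T"
  expr <- matrix(rnorm(20), 2, 10, dimnames = list(c("GA", "GB"), names(lab)))
  co <- makeCohort(expr, labels = lab)
  got <- edgeDifferentialCorrelation("GA", "GB", co, "T")
  rin <- cor(expr[1, grp], expr[2, grp])        # stats::cor oracle
  rout <- cor(expr[1, !grp], expr[2, !grp])
  expect_equal(got$r_in, rin, tolerance = 1e-12)
  expect_equal(got$r_out, rout, tolerance = 1e-12)
  expect_equal(got$delta, rin - rout, tolerance = 1e-12)

  # symmetric in its endpoints
  rev <- edgeDifferentialCorrelation("GB", "GA", co, "T")
  expect_equal(rev$delta, got$delta, tolerance = 1e-12)
})

test_that("an edge built as identical-in-subtype has delta near 1", {
  set.seed(26)
  lab <- twoGroups(30, 30)
  shared <- rnorm(30)
  expr <- rbind(GA = c(shared, rnorm(30)), GB = c(shared, rnorm(30)))
  colnames(expr) <- names(lab)
  co <- makeCohort(expr, labels = lab)
  got <- edgeDifferentialCorrelation("GA", "GB", co, "T")
  expect_gt(got$delta, 0.7)

  # identical joint distribution in both groups: delta near 0
  f <- rnorm(60)
  expr2 <- rbind(GA = f + rnorm(60, 0, 0.3), GB = f + rnorm(60, 0, 0.3))
  colnames(expr2) <- names(lab)
  got2 <- edgeDifferentialCorrelation("GA", "GB", makeCohort(expr2, labels = lab), "T")
  expect_lt(abs(got2$delta), 0.35)
})

test_that("constant vectors zero the degenerate side and are flagged", {
  lab <- twoGroups(4, 4)
  expr <- rbind(GA = c(1, 1, 1, 1, rnorm(4)), GB = rnorm(8))
  colnames(expr) <- names(lab)
  co <- makeCohort(expr, labels = lab)
  got <- edgeDifferentialCorrelation("GA", "GB", co, "T")
  expect_equal(got$r_in, 0)
  expect_true(got$degenerate)
})

test_that("the co-expression threshold implements the upper-tail order rule", {
  expect_gte(coexpressionThreshold(c(rep(0, 1000), 1.5, 1.5)), 1.5)
  d <- c(rep(0, 1000), 1.5, 1.5)
  thr <- coexpressionThreshold(d)
  expect_equal(sum(d >= thr), 2L)            # exactly the two extreme edges
  expect_equal(coexpressionThreshold(c(3, 1, 2), topFrac = 1), 1)
  expect_equal(coexpressionThreshold(5, topFrac = 0.002), 5)
})

test_that("edge delta tables agree with per-edge recomputation", {
  net <- generateNetwork(30, 4, rngSeed = 27)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 30, nSamples = c(A = 6L, B = 6L, C = 6L), targetSubtype = "B",
    seedGenes = 2L, multiProbeFrac = 0, rngSeed = 27))
  tab <- edgeDeltaTable(net, sim$cohort, "B")
  expect_equal(sum(tab$qualifies), 1L)       # floor(0.002 * E) -> top edge
  for (i in sample(nrow(tab), 5)) {
    one <- edgeDifferentialCorrelation(tab$geneA[i], tab$geneB[i],
                                       sim$cohort, "B")
    expect_equal(tab$delta[i], one$delta, tolerance = 1e-10)
  }
  expect_equal(attr(tab, "threshold"), max(tab$delta))
})
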