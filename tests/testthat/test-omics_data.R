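test_that("continuous copy-number values discretise by the +/- thresholds", {
  m <- matrix(c(0.5, -0.5, 0.1, 0.3, -0.3, NA), 6, 1,
              dimnames = list(paste0("g", 1:6), "s1"))
  d <- discretizeCNA(m)
  expect_equal(unname(d[1:5, 1]), c(1, -1, 0, 1, -1))  # cutoffs inclusive
  expect_true(is.na(d[6, 1]))
  expect_error(discretizeCNA(m, gainThreshold = -1), "gainThreshold")
})

test_that("subtype-average CNA score is the mean of discrete calls", {
  d <- matrix(c(1, 1, 0, 1,
                1, 1, 1, 1,
                0, 0, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  lab <- stats::setNames(factor(rep("T", 4)), paste0("s", 1:4))
  sc <- averageCNAScore(d, lab, "T")
  expect_equal(unname(sc), c(0.75, 1, 0))  # all-amplified gene scores 1
  expect_error(averageCNAScore(d, lab, "missing"), "no samples")
  expect_error(averageCNAScore(d * 0.5, lab, "T"), "discrete")

  # bounded in [-1, 1] on random call matrices
  set.seed(1)
  r <- matrix(sample(c(-1, 0, 1), 200, replace = TRUE), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  lab <- stats::setNames(factor(rep(c("A", "B"), 5)), paste0("s", 1:10))
  sc <- averageCNAScore(r, lab, "A")
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("CNA-expression correlation is pooled Pearson with degeneracy rules", {
  calls <- matrix(c(1, 0, 1, 0, 1, 0,
                    0, 0, 0, 0, 0, 0,
                    1, 1, 0, 0, 1, 0), 3, 6, byrow = TRUE,
                  dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:6)))
  expr <- rbind(G1 = calls[1, ],               # identical to its calls
                G2 = rnorm(6),
                G3 = -calls[3, ])              # perfectly anti-correlated
  lab <- stats::setNames(factor(rep(c("A", "B"), 3)), paste0("s", 1:6))
  co <- makeCohort(expr, calls, lab)
  r <- suppressMessages(cnaExprCorrelation(co))
  expect_equal(unname(r["G1"]), 1)
  expect_equal(unname(r["G3"]), -1)
  expect_false("G2" %in% names(r))             # constant CNA vector omitted

  # invariant to positive affine rescaling of expression
  co2 <- makeCohort(expr * 3.7 + 11, calls, lab)
  expect_equal(suppressMessages(cnaExprCorrelation(co2)), r)
})

test_that("multi-probe genes use the probe with highest absolute correlation", {
  set.seed(42)
  calls <- matrix(rep(c(1, 0), 5), 1, 10,
                  dimnames = list("G1", paste0("s", 1:10)))
  good <- calls[1, ] + rnorm(10, 0, 0.05)
  bad <- rnorm(10)
  expr <- rbind(p1 = bad, p2 = good)
  colnames(expr) <- paste0("s", 1:10)
  lab <- stats::setNames(factor(rep(c("A", "B"), 5)), paste0("s", 1:10))
  co <- suppressMessages(OmicsCohort(expr, c(p1 = "G1", p2 = "G1"),
                                     calls, lab))
  r <- suppressMessages(cnaExprCorrelation(co))
  expect_equal(unname(r["G1"]), cor(calls[1, ], good))  # stats::cor oracle
})

test_that("probe collapsing follows the selected rule and invents nothing", {
  set.seed(7)
  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(c("p1", "p2", "p3", "p4"), paste0("s", 1:10)))
  expr["p2", ] <- expr["p2", ] * 3                    # most variable for G1
  pm <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G3")

  cv <- collapseProbes(expr, pm, rule = "maxVariance")
  expect_equal(cv["G1", ], expr["p2", ])
  expect_equal(cv["G2", ], expr["p3", ])              # single probe: identity
  expect_true(all(apply(cv, 1, function(r)
    any(apply(expr, 1, function(e) isTRUE(all.equal(unname(e), unname(r))))))))

  partner <- expr["p4", ]
  cc <- collapseProbes(expr, pm, rule = "maxAbsCorrelation",
                       partner = partner)
  # chosen probe must have the larger |Pearson r| against the partner
  rs <- abs(c(cor(expr["p1", ], partner), cor(expr["p2", ], partner)))
  expect_equal(unname(attr(cc, "probe")["G1"]),
               c("p1", "p2")[which.max(rs)])
  expect_error(collapseProbes(expr, character(0)), "empty probe map")
})

test_that("cohorts round-trip through the TSV interchange format", {
  net <- generateNetwork(40, 4, rngSeed = 2)
  sim <- generateCohort(net, generatorConfig(
    nGenes = 40, nSamples = c(A = 4L, B = 4L, C = 4L),
    targetSubtype = "B", seedGenes = 2L, rngSeed = 2))
  d <- withr::local_tempdir()
  writeCohort(sim$cohort, d)
  back <- readCohort(d)
  expect_equal(back@expression, sim$cohort@expression, tolerance = 1e-9)
  expect_equal(back@cna, sim$cohort@cna, tolerance = 1e-9)
  expect_equal(back@probeMap, sim$cohort@probeMap)
  expect_equal(as.character(back@labels), as.character(sim$cohort@labels))
})

test_that("probes with excessive missingness are dropped on construction", {
  expr <- matrix(rnorm(30), 3, 10,
                 dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:10)))
  expr["p2", 1:4] <- NA
  cna <- matrix(0, 1, 10, dimnames = list("G1", paste0("s", 1:10)))
  lab <- stats::setNames(factor(rep("A", 10)), paste0("s", 1:10))
  expect_message(
    co <- OmicsCohort(expr, c(p1 = "G1", p2 = "G1", p3 = "G1"), cna, lab),
    "missing")
  expect_false("p2" %in% rownames(co@expression))
})
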