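test_that("the 3-point dilution curve fits slope, intercept and efficiency", {
  curve <- fitStandardCurve(c(100, 10, 1), c(20.00, 23.32, 26.64))
  expect_equal(curve@slope, -3.32, tolerance = 1e-9)
  expect_equal(curve@intercept, 26.64, tolerance = 1e-9)
  expect_equal(curve@r2, 1, tolerance = 1e-9)
  expect_equal(curve@efficiency, 10^(1 / 3.32) - 1, tolerance = 1e-9)
  expect_equal(curve@efficiency, 1, tolerance = 2e-3)  # ~100%
  expect_true(curve@valid)
})

test_that("percent input inverts the curve", {
  curve <- fitStandardCurve(c(100, 10, 1), c(20.00, 23.32, 26.64))
  expect_equal(percentInput(23.32, curve), 10, tolerance = 1e-6)
  expect_equal(percentInput(curve@intercept, curve), 1, tolerance = 1e-9)
  expect_equal(percentInput(curve@intercept + 2 * curve@slope, curve), 100,
               tolerance = 1e-9)
  ## identity on fitted points when R2 = 1
  expect_equal(percentInput(c(20.00, 23.32, 26.64), curve), c(100, 10, 1),
               tolerance = 1e-6)
})

test_that("noiseless points from any (a, b) are recovered exactly", {
  set.seed(31)
  for (i in 1:10) {
    a <- runif(1, 20, 35); b <- -runif(1, 2.5, 4.5)
    pct <- c(100, 10, 1, 0.1)
    curve <- fitStandardCurve(pct, a + b * log10(pct))
    expect_equal(curve@slope, b, tolerance = 1e-10)
    expect_equal(curve@intercept, a, tolerance = 1e-10)
  }
})

test_that("invalid curves are flagged and rejected downstream", {
  up <- fitStandardCurve(c(100, 10, 1), c(26, 23, 20))  # positive slope
  expect_false(up@valid)
  expect_error(percentInput(22, up), "invalid")
  expect_error(fitStandardCurve(c(100, 10), c(20, 23)), "at least 3")
  expect_error(fitStandardCurve(c(100, 10, 0), c(20, 23, 26)), "> 0")
})

test_that("efficiency is 100% exactly at slope -1/log10(2)", {
  b <- -1 / log10(2)
  curve <- fitStandardCurve(c(100, 10, 1), 30 + b * log10(c(100, 10, 1)))
  expect_equal(curve@efficiency, 1, tolerance = 1e-12)
})

test_that("group comparison matches a hand-coded Welch t test", {
  tagged <- c(4.1, 3.9, 4.0, 4.2); untagged <- c(1.0, 1.1, 0.9)
  res <- qpcrCompare(tagged, untagged)
  oracle <- welchOracle(tagged / 100, untagged / 100)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  ## symmetry: swapping groups negates t, preserves p
  swap <- qpcrCompare(untagged, tagged)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  expect_equal(res$sem_tagged, sd(tagged / 100) / 2, tolerance = 1e-12)
})

test_that("degenerate comparisons: equal groups and zero variance", {
  same <- qpcrCompare(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- qpcrCompare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(const$p, 1)
  expect_equal(qpcrCompare(c(1, 1, 1), c(1, 1, 1))$sem_tagged, 0)
  expect_error(qpcrCompare(3, c(1, 2)), ">= 2 replicates")
})

test_that("noiseless simulated Cq values invert to the true percents", {
  cfg <- simulationConfig(seed = 6L, qpcrSigma = 0)
  q <- simulateQpcr(cfg)
  res <- analyzeQpcr(q$measurements)
  expect_equal(res$slope, rep(-3.32, 4), tolerance = 1e-9)
  expect_equal(res$mean_tagged * 100, q$truth$tagged_percent,
               tolerance = 1e-9)
  expect_equal(res$fold_change,
               q$truth$tagged_percent / q$truth$untagged_percent,
               tolerance = 1e-9)
})

test_that("a 4x vs 1x contrast is detected in nearly all noisy replicates", {
  ## power of the Welch comparison at sigma = 0.1 Cq, 4 vs 3 replicates
  hits <- 0L
  for (s in 1:200) {
    cfg <- simulationConfig(seed = s, qpcrSigma = 0.1,
                            taggedPercent = 4, untaggedPercent = 1)
    q <- simulateQpcr(cfg)
    res <- analyzeQpcr(q$measurements)
    if (res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("array spots rank by replicate mean with stable ties", {
  spots <- data.frame(
    peptide_id = c("P2", "P1", "P3"), histone = "H3",
    modifications = c("K9ac", "K14ac", "K9ac+K14ac"),
    rep1 = c(0.90, 0.90, 0.20), rep2 = c(1.00, 1.00, 0.20),
    rep3 = c(0.95, 0.95, 0.20), rep4 = c(0.95, 0.95, 0.20),
    stringsAsFactors = FALSE)
  out <- rankArray(spots, topK = Inf)
  expect_equal(out$mean_intensity[1], 0.95)
  expect_equal(out$peptide_id, c("P1", "P2", "P3"))  # tie broken by id
  expect_equal(nrow(out), 3L)
  ## topK truncates
  expect_equal(nrow(rankArray(spots, topK = 2)), 2L)
  ## missing replicate names the spot
  broken <- spots; broken$rep2[1] <- NA
  expect_error(rankArray(broken), "P2")
})

test_that("raw-scale arrays are min-max normalized, [0,1] tables pass through", {
  spots <- data.frame(peptide_id = c("A", "B"), histone = "H3",
                      modifications = "K9ac",
                      rep1 = c(1000, 200), rep2 = c(900, 100),
                      stringsAsFactors = FALSE)
  out <- rankArray(spots, topK = Inf)
  expect_equal(max(out$mean_intensity), (1000 / 2 + 900 / 2 - 100) / 900,
               tolerance = 1e-12)
  inUnit <- data.frame(peptide_id = "A", histone = "H3",
                       modifications = "K9ac", rep1 = 0.4, rep2 = 0.6,
                       stringsAsFactors = FALSE)
  expect_equal(rankArray(inUnit, topK = Inf)$mean_intensity, 0.5)
})

test_that("modified residues absent from the histone sequence are flagged", {
  histones <- readHistoneFasta(system.file("extdata",
                                           "synthetic_histones.fasta",
                                           package = "chipOccupancy"))
  spots <- data.frame(
    peptide_id = c("P1", "P2"), histone = c("H4", "H3"),
    modifications = c("R3me2s+K5ac+K8ac+K12ac", "K9ac+K14ac"),
    rep1 = c(0.9, 0.95), rep2 = c(0.9, 0.95), stringsAsFactors = FALSE)
  out <- rankArray(spots, topK = Inf, histoneSeqs = histones)
  expect_equal(out$non_conserved[out$peptide_id == "P1"], "R3me2s")
  expect_equal(out$non_conserved[out$peptide_id == "P2"], "")
  p <- parseModifications(c("K9ac", "R3me2s", "S10P"))
  expect_equal(p$position, c(9L, 3L, 10L))
  expect_equal(p$residue, c("K", "R", "S"))
  expect_error(parseModifications("notamod"), "cannot parse")
})

test_that("noise-free simulated arrays rank exactly by affinity", {
  cfg <- simulationConfig(seed = 8L, arrayNoiseSd = 0)
  a <- simulateArray(cfg)
  out <- rankArray(a$spots, topK = Inf)
  truthOrder <- a$truth[order(-a$truth$affinity, a$truth$peptide_id), ]
  expect_equal(out$peptide_id, truthOrder$peptide_id)
  expect_equal(out$mean_intensity, truthOrder$affinity)
  expect_equal(out$modifications[1], "K9ac+K14ac")
  expect_equal(out$mean_intensity[1], 0.95)
})
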