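test_that("region signal sums per-base depth (brute-force oracle)", {
  tr <- toyTrack(chr1 = rep(3, 100))
  expect_equal(regionSignal(tr, list(chrom = "chr1", start = 11, end = 20)),
               30)
  ## zero depth over the queried span reads as 0
  tr0 <- toyTrack(chr1 = c(rep(0, 90), rep(1, 10)))
  expect_equal(regionSignal(tr0, list(chrom = "chr1", start = 1, end = 50)),
               0)
  set.seed(11)
  vec <- sample(0:50, 1000, replace = TRUE)
  trr <- toyTrack(chr1 = vec)
  expect_equal(regionSignal(trr, list(chrom = "chr1", start = 137,
                                      end = 840)),
               bruteSum(vec, 137, 840))
  expect_error(regionSignal(trr, list(chrom = "chr1", start = 900,
                                      end = 1100)),
               "off chromosome")
  expect_error(regionSignal(trr, list(chrom = "chrZ", start = 1, end = 2)),
               "unknown chromosome")
})

test_that("coverage tracks load from bedGraph, BED reads and BAM", {
  cs <- c(chr1 = 200L)
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100\t5", "chr1\t100\t150\t2"), bg)
  tr <- coverageFromBedGraph(bg, cs)
  expect_equal(regionSignal(tr, list(chrom = "chr1", start = 1, end = 200)),
               5 * 100 + 2 * 50)
  expect_equal(regionSignal(tr, list(chrom = "chr1", start = 100,
                                     end = 101)), 7)
  expect_equal(totalSignal(tr), 600)

  ## bedGraph round-trip is exact for integer depths
  out <- tempfile(fileext = ".bedGraph")
  writeBedGraph(tr, out)
  tr2 <- coverageFromBedGraph(out, cs)
  expect_identical(trackCoverage(tr2), trackCoverage(tr))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t50\tr1\t0\t+", "chr1\t25\t75\tr2\t0\t-"), bed)
  trb <- coverageFromBed(bed, cs)
  expect_equal(regionSignal(trb, list(chrom = "chr1", start = 26,
                                      end = 50)), 50)

  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:200",
    paste("r1", 0, "chr1", 1, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "chr1", 26, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  trm <- coverageFromBam(bam, cs)
  expect_equal(as.list(trackCoverage(trm)), as.list(trackCoverage(trb)),
               ignore_attr = TRUE)
  expect_equal(totalSignal(trm), totalSignal(trb))
})

test_that("fold enrichment follows the normalized ratio formula", {
  expect_equal(foldEnrichment(200, 1e6, 100, 1e6, 0), 2.0)
  expect_equal(foldEnrichment(0, 1e6, 100, 1e6, 1), 1 / 101)
  ## scale invariance with pseudocount 0
  set.seed(3)
  for (i in 1:20) {
    ip <- runif(1, 0, 1e4); inp <- runif(1, 1, 1e4)
    tot <- runif(2, 1e5, 1e7); cc <- runif(1, 0.1, 10)
    expect_equal(foldEnrichment(ip * cc, tot[1] * cc, inp * cc,
                                tot[2] * cc, 0),
                 foldEnrichment(ip, tot[1], inp, tot[2], 0))
  }
  expect_error(foldEnrichment(-1, 1, 1, 1, 0), "negative")
  expect_error(foldEnrichment(1, 0, 1, 1, 0), "> 0")
  expect_equal(foldEnrichment(10, 1e6, 0, 1e6, 0), Inf)
})

test_that("strong-peak scan finds planted plateaus and rejects flat signal", {
  cfg <- enrichmentConfig(pseudocount = 0)
  flat <- toyTrack(chr1 = rep(10, 2000))
  same <- strongPeakScan(flat, flat, list(chrom = "chr1", start = 501,
                                          end = 1100), cfg)
  expect_false(same$strong)
  expect_equal(same$max_window_fe, 1)

  ## 5x plateau over [701, 900] within a 600 bp region on flat input
  ip <- rep(10, 2000); ip[701:900] <- 50
  ipT <- toyTrack(chr1 = ip)
  sc <- strongPeakScan(ipT, flat, list(chrom = "chr1", start = 501,
                                       end = 1100), cfg)
  expect_true(sc$strong)
  expect_gte(sc$summit, 701)
  expect_lte(sc$summit, 900)
  ## enumerate all windows by hand: the summit is the center of the
  ## leftmost maximal-FE window
  starts <- seq(501, 1100 - 200 + 1, by = 50)
  fe <- vapply(starts, function(s) {
    (bruteSum(ip, s, s + 199) / sum(ip)) / (200 * 10 / sum(rep(10, 2000)))
  }, numeric(1))
  best <- starts[which.max(fe)]
  expect_equal(sc$summit, as.integer((best + best + 199) %/% 2))

  ## region shorter than the window: a single window covering the region
  short <- strongPeakScan(ipT, flat, list(chrom = "chr1", start = 751,
                                          end = 850), cfg)
  expect_equal(short$summit, as.integer((751 + 850) %/% 2))
  expect_true(short$strong)
})

test_that("regions rank by fold enrichment with threshold filters", {
  ## 3 genes of 300 bp in a 30 kb genome, planted local ratios 1, 2.5, 6
  len <- 30000L
  genes <- toyGenes("chr1", c(1001, 11001, 21001), c(1300, 11300, 21300),
                    "+", c("gA", "gB", "gC"))
  p <- partitionGenome(genes, c(chr1 = len))
  input <- rep(10, len)
  ip <- rep(10, len)
  ip[11001:11300] <- 25; ip[21001:21300] <- 60
  ipT <- toyTrack(chr1 = ip); inT <- toyTrack(chr1 = input)
  cfg <- enrichmentConfig(pseudocount = 0)
  tab <- enrichRegions(ipT, inT, p, cfg)

  ## brute-force oracle for every region's fold enrichment
  for (i in seq_len(nrow(tab))) {
    expected <- (bruteSum(ip, tab$start[i], tab$end[i]) / sum(ip)) /
      (bruteSum(input, tab$start[i], tab$end[i]) / sum(input))
    expect_equal(tab$fold_enrichment[i], expected)
  }
  expect_false(is.unsorted(rev(tab$fold_enrichment)))
  orf <- tab[tab$type == "ORF", ]
  expect_equal(orf$region_id, c("gC", "gB", "gA"))
  expect_equal(nrow(filterEnriched(orf, 2)), 2L)
  expect_equal(nrow(filterEnriched(orf, 4)), 1L)
  ## ranking is a permutation of the partition regions
  expect_setequal(tab$region_id, partitionReport(p)$region_id)
  expect_equal(anyDuplicated(tab$region_id), 0L)
})

test_that("fold enrichment is invariant to depth rescaling of one track", {
  set.seed(5)
  vec <- sample(5:40, 5000, replace = TRUE)
  genes <- toyGenes("chr1", c(501, 2501), c(1500, 3500), "+")
  p <- partitionGenome(genes, c(chr1 = 5000L))
  cfg <- enrichmentConfig(pseudocount = 0)
  t1 <- enrichRegions(toyTrack(chr1 = vec * 7), toyTrack(chr1 = vec), p,
                      cfg, strongScan = FALSE)
  t2 <- enrichRegions(toyTrack(chr1 = vec), toyTrack(chr1 = vec), p,
                      cfg, strongScan = FALSE)
  expect_equal(t1$fold_enrichment, t2$fold_enrichment)
})

test_that("bins follow half-open thresholds with a cumulative option", {
  tab <- data.frame(region_id = sprintf("r%d", 1:5),
                    fold_enrichment = c(1, 2, 3.9, 6, 9))
  cfg <- enrichmentConfig()
  expect_equal(binCounts(tab, cfg),
               c("<2" = 1L, "[2,4)" = 2L, "[4,6)" = 0L, "[6,8)" = 1L,
                 ">=8" = 1L))
  cfgc <- enrichmentConfig(cumulativeBins = TRUE)
  expect_equal(binCounts(tab, cfgc),
               c(">=2" = 4L, ">=4" = 2L, ">=6" = 2L, ">=8" = 1L))
})

test_that("low-input regions are flagged, not dropped", {
  len <- 4000L
  genes <- toyGenes("chr1", c(501, 2501), c(1500, 3500), "+")
  p <- partitionGenome(genes, c(chr1 = len))
  input <- rep(20, len); input[501:1500] <- 0.5
  tab <- enrichRegions(toyTrack(chr1 = rep(20, len)),
                       toyTrack(chr1 = input), p,
                       enrichmentConfig(), strongScan = FALSE)
  expect_true(tab$low_input_flag[tab$region_id == "g1"])
  expect_false(tab$low_input_flag[tab$region_id == "g2"])
  expect_equal(nrow(tab), nrow(partitionReport(p)))
})
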