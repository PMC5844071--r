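test_that("single-flank classes follow summit proximity on long regions", {
  ## tandem genes, 1200 bp gap (longer than bothFlankLen): only the flank
  ## within dMax of the summit is addressed
  r <- toyRegion(501, 1700, "+", "+")
  near_left <- classifyIntergenic(r, 520)
  expect_equal(near_left$class, "TERMINATOR_SINGLE")
  expect_equal(near_left$terminator_genes, "L")
  near_right <- classifyIntergenic(r, 1650)
  expect_equal(near_right$class, "PROMOTER_SINGLE")
  expect_equal(near_right$promoter_genes, "R")
  expect_equal(classifyIntergenic(r, 1100)$class, "UNCLASSIFIED")
})

test_that("short regions address both flanks regardless of summit", {
  ## divergent orientation: both abutting ends are 5'
  div <- toyRegion(1001, 1400, "-", "+")
  expect_equal(classifyIntergenic(div, 1010)$class,
               "BIDIRECTIONAL_PROMOTER")
  expect_setequal(classifyIntergenic(div, 1200)$promoter_genes,
                  c("L", "R"))
  ## convergent orientation: both 3'
  conv <- toyRegion(1001, 1400, "+", "-")
  expect_equal(classifyIntergenic(conv, 1200)$class, "SHARED_TERMINATOR")
  ## tandem: one 3' and one 5'
  tand <- toyRegion(1001, 1400, "+", "+")
  got <- classifyIntergenic(tand, 1200)
  expect_equal(got$class, "PROMOTER_TERMINATOR_OVERLAP")
  expect_equal(got$promoter_genes, "R")
  expect_equal(got$terminator_genes, "L")
})

test_that("convergent genes with a summit near both ends share a terminator", {
  ## 500 bp region, summit equidistant (250 <= dMax) from both ends
  conv <- toyRegion(1001, 1500, "+", "-")
  expect_equal(classifyIntergenic(conv, 1250)$class, "SHARED_TERMINATOR")
})

test_that("classifier agrees with the truth-table oracle over all orientations and summits", {
  cfg <- classifierConfig()
  for (len in c(400L, 3000L)) {
    region_end <- 1000L + len
    for (ls in c("+", "-")) for (rs in c("+", "-")) {
      r <- toyRegion(1001L, region_end, ls, rs)
      for (summit in seq(1001L, region_end, by = 50L)) {
        expect_equal(classifyIntergenic(r, summit, cfg)$class,
                     classifyOracle(r, summit),
                     info = sprintf("len=%d %s%s summit=%d",
                                    len, ls, rs, summit))
      }
    }
  }
})

test_that("classification is symmetric under reverse complement", {
  flip <- c("+" = "-", "-" = "+")
  cfg <- classifierConfig()
  for (len in c(400L, 3000L)) {
    e <- 1000L + len
    total <- 1000L + e  # mirror within [1, total]
    for (ls in c("+", "-")) for (rs in c("+", "-")) {
      r <- toyRegion(1001L, e, ls, rs)
      ## mirrored region: flanks swap sides, strands flip
      m <- toyRegion(total - e + 1L, total - 1001L + 1L,
                     flip[[rs]], flip[[ls]])
      for (summit in seq(1001L, e, by = 100L)) {
        a <- classifyIntergenic(r, summit, cfg)$class
        b <- classifyIntergenic(m, total - summit + 1L, cfg)$class
        expect_equal(a, b)
      }
    }
  }
})

test_that("edge regions classify on their single flank", {
  left_only <- toyRegion(501, 1700, "+", NA)
  expect_equal(classifyIntergenic(left_only, 520)$class,
               "TERMINATOR_SINGLE")
  expect_equal(classifyIntergenic(left_only, 1600)$class, "UNCLASSIFIED")
  right_only <- toyRegion(501, 1700, NA, "-")
  expect_equal(classifyIntergenic(right_only, 1650)$class,
               "TERMINATOR_SINGLE")
  expect_error(classifyIntergenic(toyRegion(501, 700, "+", "+"), 800),
               "outside")
})

test_that("classifyAll assigns every region once and errors on unknown ids", {
  sim <- simulateGenome(simulationConfig(seed = 2L))
  truth <- sim$intergenicTruth
  tab <- data.frame(region_id = truth$region_id, type = "INTERGENIC",
                    summit = truth$summit, stringsAsFactors = FALSE)
  res <- classifyAll(tab, sim$partition)
  expect_equal(nrow(res$assignments), nrow(truth))
  expect_equal(sum(res$counts), nrow(truth))
  got <- setNames(res$assignments$class, res$assignments$region_id)
  expect_equal(unname(got[truth$region_id]), truth$class)
  ## planted role genes recovered
  gotProm <- setNames(res$assignments$promoter_genes,
                      res$assignments$region_id)
  expect_equal(unname(gotProm[truth$region_id]), truth$promoter_genes)

  bad <- data.frame(region_id = "IG_nowhere_0001", type = "INTERGENIC",
                    summit = 5L)
  expect_error(classifyAll(bad, sim$partition), "absent from partition")

  empty <- classifyAll(tab[0, ], sim$partition)
  expect_equal(sum(empty$counts), 0L)
})

test_that("regions without a strong-peak summit fall back to the midpoint", {
  genes <- toyGenes("chr1", c(101, 1001), c(500, 1500), c("-", "+"))
  p <- partitionGenome(genes, c(chr1 = 2000L))
  ig <- intergenicRegions(p)
  internal <- mcols(ig)$region_id[!mcols(ig)$edge]
  tab <- data.frame(region_id = internal, type = "INTERGENIC",
                    summit = NA_integer_)
  res <- classifyAll(tab, p)
  expect_true(res$assignments$midpoint_fallback)
  expect_equal(res$assignments$summit, as.integer((501 + 1000) %/% 2))
  expect_equal(res$assignments$class, "BIDIRECTIONAL_PROMOTER")
})

test_that("combined promoter+ORF and ORF+terminator categories", {
  assignments <- data.frame(
    region_id = c("i1", "i2", "i3", "i4"),
    class = c("PROMOTER_SINGLE", "BIDIRECTIONAL_PROMOTER",
              "TERMINATOR_SINGLE", "PROMOTER_TERMINATOR_OVERLAP"),
    promoter_genes = c("gA", "gB,gC", "", "gE"),
    terminator_genes = c("", "", "gD", "gF"),
    stringsAsFactors = FALSE)
  cmb <- combineOrfFlanks(c("gA", "gC", "gD", "gE", "gF", "gZ"),
                          assignments)
  expect_setequal(cmb$promoter_plus_orf, c("gA", "gC"))
  ## overlap-class genes do not qualify either category
  expect_setequal(cmb$orf_plus_terminator, "gD")
  ## an enriched ORF with no enriched flank is in neither
  expect_false("gZ" %in% unlist(cmb))
})

test_that("synthetic composites are recovered end to end on truth summits", {
  sim <- simulateGenome(simulationConfig(seed = 4L))
  truth <- sim$intergenicTruth
  tab <- data.frame(region_id = truth$region_id, type = "INTERGENIC",
                    summit = truth$summit, stringsAsFactors = FALSE)
  res <- classifyAll(tab, sim$partition)
  cmb <- combineOrfFlanks(sim$genicTruth$gene_id, res$assignments)
  expect_equal(cmb$promoter_plus_orf, sim$composites$promoter_plus_orf)
  expect_equal(cmb$orf_plus_terminator, sim$composites$orf_plus_terminator)
  expect_gte(length(cmb$promoter_plus_orf), 3L)
  expect_gte(length(cmb$orf_plus_terminator), 2L)
})
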