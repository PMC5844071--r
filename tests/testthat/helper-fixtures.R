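suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## GRanges gene catalog from parallel vectors (1-based closed coordinates)
toyGenes <- function(chrom, start, end, strand = "+",
                     gene_id = sprintf("g%d", seq_along(start))) {
  GRanges(chrom, IRanges(start, end), strand = strand,
          gene_id = gene_id, description = NA_character_)
}

## CoverageTrack from plain per-base numeric vectors (one per chromosome)
toyTrack <- function(...) {
  vecs <- list(...)
  cs <- setNames(vapply(vecs, length, integer(1)), names(vecs))
  cov <- as(lapply(vecs, Rle), "SimpleRleList")
  coverageTrack(cov, cs)
}

## brute-force per-base depth sum (independent of Rle/Views machinery)
bruteSum <- function(vec, start, end) {
  total <- 0
  for (i in start:end) total <- total + vec[i]
  total
}

## intergenic region stub for the classifier (list form)
toyRegion <- function(start, end, leftStrand = NA, rightStrand = NA,
                      leftGene = if (is.na(leftStrand)) NA_character_ else "L",
                      rightGene = if (is.na(rightStrand)) NA_character_ else "R") {
  list(start = start, end = end,
       left_gene = leftGene, left_strand = leftStrand,
       right_gene = rightGene, right_strand = rightStrand)
}

## independent truth-table oracle for the positional classifier: addressing
## by plain arithmetic, then an explicit lookup from addressed gene ends
classifyOracle <- function(region, summit, dMax = 300, bothFlankLen = 600) {
  width <- region$end - region$start + 1
  ends <- character(0)
  if (!is.na(region$left_gene)) {
    d <- summit - (region$start - 1)
    if (d <= dMax || width <= bothFlankLen)
      ends <- c(ends, if (region$left_strand == "+") "3p" else "5p")
  }
  if (!is.na(region$right_gene)) {
    d <- (region$end + 1) - summit
    if (d <= dMax || width <= bothFlankLen)
      ends <- c(ends, if (region$right_strand == "+") "5p" else "3p")
  }
  key <- paste(sort(ends), collapse = "+")
  lookup <- c(
    "5p" = "PROMOTER_SINGLE",
    "3p" = "TERMINATOR_SINGLE",
    "5p+5p" = "BIDIRECTIONAL_PROMOTER",
    "3p+3p" = "SHARED_TERMINATOR",
    "3p+5p" = "PROMOTER_TERMINATOR_OVERLAP")
  if (key == "") "UNCLASSIFIED" else unname(lookup[key])
}

## small but feasible simulation: fewer planted classes fit a short genome
smallSimConfig <- function(seed = 1L, ...) {
  simulationConfig(
    seed = seed, nGenes = 60L, nChroms = 2L,
    plantedClassCounts = c(PROMOTER_SINGLE = 2L, TERMINATOR_SINGLE = 1L,
                           BIDIRECTIONAL_PROMOTER = 1L,
                           SHARED_TERMINATOR = 1L,
                           PROMOTER_TERMINATOR_OVERLAP = 1L),
    compositePromoterOrf = 1L, compositeOrfTerminator = 1L, ...)
}

## hand-coded Welch two-sample two-sided t test (textbook formulas)
welchOracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## exact hypergeometric upper tail by combinatorial sum (no phyper)
hyperOracle <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

md5OfDir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(unname(tools::md5sum(files)),
           sub(paste0("^", dir, "/?"), "", files))
}
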