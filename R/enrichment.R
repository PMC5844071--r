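#' Configure region-level enrichment calling
#'
#' @param pseudocount depth-units added to each region's IP and input sums
#'   before the ratio (default 1).
#' @param binThresholds strictly increasing fold-enrichment thresholds
#'   (default \code{c(2, 4, 6, 8)}).
#' @param window strong-peak scan window width, bp (default 200).
#' @param step scan step, bp (default 50).
#' @param minWindowIpDepth minimum IP depth sum in the maximal window for a
#'   strong-peak call (default 5).
#' @param lowInputFraction regions with input density below this fraction of
#'   the genome-mean input density are flagged (default 0.1).
#' @param cumulativeBins report bin counts cumulatively (>= t) instead of
#'   over half-open intervals [t_i, t_{i+1}) (default FALSE).
#' @return An [EnrichmentConfig-class].
#' @export
enrichmentConfig <- function(pseudocount = 1, binThresholds = c(2, 4, 6, 8),
                             window = 200L, step = 50L,
                             minWindowIpDepth = 5, lowInputFraction = 0.1,
                             cumulativeBins = FALSE) {
  new("EnrichmentConfig", pseudocount = pseudocount,
      binThresholds = as.numeric(binThresholds),
      window = as.integer(window), step = as.integer(step),
      minWindowIpDepth = minWindowIpDepth,
      lowInputFraction = lowInputFraction,
      cumulativeBins = cumulativeBins)
}

#' Library-normalized IP/INPUT fold enrichment
#'
#' Computes \code{((ip + p) / ipTotal) / ((input + p) / inputTotal)} where
#' \code{p} is the pseudocount. With pseudocount 0 and zero input the result
#' is \code{Inf}; callers flag such regions via the low-input check rather
#' than dropping them.
#'
#' @param ipSum,inputSum region depth sums (vectorized).
#' @param ipTotal,inputTotal total track signals (> 0).
#' @param pseudocount non-negative (default 0).
#' @return Numeric vector of fold enrichments.
#' @export
foldEnrichment <- function(ipSum, ipTotal, inputSum, inputTotal,
                           pseudocount = 0) {
  if (any(ipSum < 0) || any(inputSum < 0) || pseudocount < 0)
    stop("negative input to foldEnrichment")
  if (ipTotal <= 0 || inputTotal <= 0)
    stop("track totals must be > 0")
  ((ipSum + pseudocount) / ipTotal) / ((inputSum + pseudocount) / inputTotal)
}

.binLabels <- function(thresholds) {
  n <- length(thresholds)
  upper <- c(thresholds[-1], Inf)
  c(sprintf("<%g", thresholds[1]),
    ifelse(is.finite(upper),
           sprintf("[%g,%g)", thresholds, upper),
           sprintf(">=%g", thresholds)))
}

.assignBins <- function(fe, thresholds) {
  cut(fe, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = .binLabels(thresholds))
}

#' Sliding-window strong-peak scan over one region
#'
#' Slides windows of configured width across the region (a region shorter
#' than the window is scanned as a single window covering it). Each window's
#' fold enrichment is computed from its IP and input sums with the configured
#' pseudocount. The call is strong when the maximal window reaches the first
#' bin threshold and its IP depth sum reaches \code{minWindowIpDepth}; the
#' summit is the center of the maximal window (ties resolved leftmost).
#'
#' @param ipTrack,inputTrack [CoverageTrack-class] objects.
#' @param region \code{list(chrom=, start=, end=)} or a length-1
#'   \code{GRanges}.
#' @param config an [EnrichmentConfig-class].
#' @return \code{list(strong = logical, summit = integer or NA,
#'   max_window_fe = numeric)}.
#' @export
strongPeakScan <- function(ipTrack, inputTrack, region,
                           config = enrichmentConfig()) {
  if (methods::is(region, "GRanges"))
    region <- list(chrom = as.character(seqnames(region))[1],
                   start = start(region)[1], end = end(region)[1])
  w <- config@window; stp <- config@step
  s <- region$start; e <- region$end
  if (e - s + 1L < w) {
    starts <- s; ends <- e
  } else {
    starts <- seq.int(s, e - w + 1L, by = stp)
    ends <- starts + w - 1L
  }
  ipCov <- trackCoverage(ipTrack)[[region$chrom]]
  inCov <- trackCoverage(inputTrack)[[region$chrom]]
  if (s < 1L || e > length(ipCov) || e > length(inCov))
    stop("region off chromosome ", region$chrom)
  ipSums <- viewSums(Views(ipCov, starts, ends))
  inSums <- viewSums(Views(inCov, starts, ends))
  fe <- foldEnrichment(ipSums, totalSignal(ipTrack),
                       inSums, totalSignal(inputTrack),
                       config@pseudocount)
  i <- which.max(fe)
  strong <- fe[i] >= config@binThresholds[1] &&
    ipSums[i] >= config@minWindowIpDepth
  list(strong = strong,
       summit = as.integer((starts[i] + ends[i]) %/% 2L),
       max_window_fe = unname(fe[i]))
}

#' Rank genome regions by IP/INPUT fold enrichment
#'
#' Produces one record per partition region (genic and intergenic), sorted by
#' fold enrichment in descending order (ties broken by region id). Bin labels
#' follow the configured thresholds; the strong-peak scan supplies a summit
#' for strong regions. Regions whose input density falls below
#' \code{lowInputFraction} times the genome-mean input density are flagged,
#' not dropped.
#'
#' @param ipTrack,inputTrack [CoverageTrack-class] objects.
#' @param partition a [GenomePartition-class].
#' @param config an [EnrichmentConfig-class].
#' @param strongScan run the per-region strong-peak scan (default TRUE).
#' @return data.frame with columns region_id, chrom, start, end (1-based
#'   inclusive), type, ip_sum, input_sum, fold_enrichment, bin, strong_peak,
#'   summit, low_input_flag.
#' @export
enrichRegions <- function(ipTrack, inputTrack, partition,
                          config = enrichmentConfig(), strongScan = TRUE) {
  rep <- partitionReport(partition)
  if (!nrow(rep)) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), ip_sum = numeric(0),
                      input_sum = numeric(0), fold_enrichment = numeric(0),
                      bin = character(0), strong_peak = logical(0),
                      summit = integer(0), low_input_flag = logical(0)))
  }
  gr <- GRanges(rep$chrom, IRanges(rep$start, rep$end))
  ipSum <- regionSignal(ipTrack, gr)
  inSum <- regionSignal(inputTrack, gr)
  fe <- foldEnrichment(ipSum, totalSignal(ipTrack),
                       inSum, totalSignal(inputTrack), config@pseudocount)
  genomeLen <- sum(as.numeric(chromSizes(partition)))
  meanInputDensity <- totalSignal(inputTrack) / genomeLen
  lowInput <- (inSum / (rep$end - rep$start + 1)) <
    config@lowInputFraction * meanInputDensity
  strong <- logical(nrow(rep)); summit <- rep(NA_integer_, nrow(rep))
  if (strongScan) {
    for (i in seq_len(nrow(rep))) {
      sc <- strongPeakScan(ipTrack, inputTrack,
                           list(chrom = rep$chrom[i], start = rep$start[i],
                                end = rep$end[i]), config)
      strong[i] <- sc$strong
      if (sc$strong) summit[i] <- sc$summit
    }
  }
  out <- data.frame(
    region_id = rep$region_id, chrom = rep$chrom,
    start = rep$start, end = rep$end, type = rep$type,
    ip_sum = ipSum, input_sum = inSum, fold_enrichment = fe,
    bin = as.character(.assignBins(fe, config@binThresholds)),
    strong_peak = strong, summit = summit, low_input_flag = lowInput,
    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_enrichment, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter an enrichment table
#'
#' @param table output of [enrichRegions()].
#' @param minFe minimum fold enrichment (default 2).
#' @param strongOnly also require a strong-peak call (default FALSE).
#' @param type optionally restrict to "ORF" or "INTERGENIC".
#' @export
filterEnriched <- function(table, minFe = 2, strongOnly = FALSE,
                           type = NULL) {
  keep <- table$fold_enrichment >= minFe
  if (strongOnly) keep <- keep & table$strong_peak
  if (!is.null(type)) keep <- keep & table$type == type
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count regions per fold-enrichment bin
#'
#' @param table output of [enrichRegions()].
#' @param config an [EnrichmentConfig-class]; with
#'   \code{cumulativeBins = TRUE} counts are of regions at or above each
#'   threshold, mirroring figure legends that report ">= t" site counts.
#' @return named integer vector of counts.
#' @export
binCounts <- function(table, config = enrichmentConfig()) {
  t <- config@binThresholds
  if (config@cumulativeBins) {
    counts <- vapply(t, function(x) sum(table$fold_enrichment >= x),
                     integer(1))
    stats::setNames(counts, sprintf(">=%g", t))
  } else {
    labs <- .binLabels(t)
    counts <- table(factor(as.character(.assignBins(table$fold_enrichment, t)),
                           levels = labs))
    stats::setNames(as.integer(counts), labs)
  }
}

#' Write an enrichment report TSV
#'
#' The header comment records the thresholds and pseudocount, because
#' downstream counts depend on them.
#'
#' @param table output of [enrichRegions()].
#' @param path output path.
#' @param config the [EnrichmentConfig-class] used.
#' @export
writeEnrichmentReport <- function(table, path,
                                  config = enrichmentConfig()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# chipOccupancy %s | pseudocount=%g | binThresholds=%s | window=%d | step=%d | minWindowIpDepth=%g | lowInputFraction=%g",
    as.character(utils::packageVersion("chipOccupancy")),
    config@pseudocount,
    paste(config@binThresholds, collapse = ","),
    config@window, config@step, config@minWindowIpDepth,
    config@lowInputFraction), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
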