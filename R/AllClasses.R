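#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame Rle runValue
#' @importFrom IRanges IRanges Views viewSums ranges reduce gaps
#' @importFrom GenomicRanges GRanges seqnames start end width strand coverage
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenomePartition: genic/intergenic tiling of a genome
#'
#' Holds the input gene catalog together with the derived partition of every
#' chromosome into merged genic spans and the intergenic gaps between them.
#' Intergenic regions carry the identity and strand of the nearest gene on
#' each side; gaps at scaffold ends are flagged \code{edge} and have a single
#' flank.
#'
#' @slot genes \code{GRanges} of the input gene models (metadata column
#'   \code{gene_id}, optional \code{description}).
#' @slot genic \code{GRanges} of merged genic spans (\code{region_id},
#'   \code{member_ids}).
#' @slot intergenic \code{GRanges} of intergenic regions (\code{region_id},
#'   \code{left_gene}, \code{left_strand}, \code{right_gene},
#'   \code{right_strand}, \code{edge}).
#' @slot chromSizes named integer vector of chromosome lengths.
#' @slot minIntergenicLength integer; gaps shorter than this were dropped.
#'
#' @seealso [partitionGenome()]
#' @export
setClass("GenomePartition",
  slots = c(
    genes = "GRanges",
    genic = "GRanges",
    intergenic = "GRanges",
    chromSizes = "integer",
    minIntergenicLength = "integer"
  )
)

setValidity("GenomePartition", function(object) {
  msg <- character()
  cs <- object@chromSizes
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    msg <- c(msg, "chromSizes must be uniquely named")
  for (gr in list(object@genic, object@intergenic)) {
    if (length(gr)) {
      bad <- !(as.character(seqnames(gr)) %in% names(cs))
      if (any(bad))
        msg <- c(msg, "region on chromosome absent from chromSizes")
      else if (any(end(gr) > cs[as.character(seqnames(gr))]))
        msg <- c(msg, "region extends beyond chromosome length")
    }
  }
  ig <- object@intergenic
  if (length(ig)) {
    noFlank <- is.na(mcols(ig)$left_gene) & is.na(mcols(ig)$right_gene)
    if (any(noFlank))
      msg <- c(msg, "intergenic region with no flanking gene")
  }
  if (length(msg)) msg else TRUE
})

#' CoverageTrack: per-base sequencing depth by chromosome
#'
#' A thin wrapper around an \code{RleList} of per-base depths with the total
#' signal (sum of all depth values) cached as a library-size proxy. Spans
#' absent from the source file read as depth 0; every chromosome in the size
#' table is represented.
#'
#' @slot cov \code{SimpleRleList} of non-negative per-base depths.
#' @slot totalSignal numeric; sum of all depths (must be > 0).
#'
#' @seealso [coverageTrack()], [coverageFromBedGraph()], [regionSignal()]
#' @export
setClass("CoverageTrack",
  slots = c(cov = "SimpleRleList", totalSignal = "numeric")
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@totalSignal) != 1L || !is.finite(object@totalSignal))
    msg <- c(msg, "totalSignal must be a single finite number")
  else if (object@totalSignal <= 0)
    msg <- c(msg, "totalSignal must be > 0")
  if (any(vapply(object@cov, function(r) any(runValue(r) < 0), logical(1))))
    msg <- c(msg, "negative depth values")
  if (length(msg)) msg else TRUE
})

#' EnrichmentConfig: parameters of region-level fold-enrichment calling
#'
#' @slot pseudocount numeric, depth-units added to each region's IP and input
#'   sums before the ratio (default 1; guards division by zero).
#' @slot binThresholds strictly increasing fold-enrichment thresholds
#'   (default 2, 4, 6, 8) used for bin labels.
#' @slot window integer, strong-peak scan window width in bp (default 200).
#' @slot step integer, scan step in bp (default 50).
#' @slot minWindowIpDepth numeric, minimum IP depth sum in the maximal window
#'   for a strong-peak call (default 5).
#' @slot lowInputFraction numeric; regions whose input density falls below
#'   this fraction of the genome-mean input density are flagged (default 0.1).
#' @slot cumulativeBins logical; when TRUE bin counts are reported
#'   cumulatively (>= t) rather than over half-open intervals.
#'
#' @seealso [enrichmentConfig()], [enrichRegions()]
#' @export
setClass("EnrichmentConfig",
  slots = c(
    pseudocount = "numeric",
    binThresholds = "numeric",
    window = "integer",
    step = "integer",
    minWindowIpDepth = "numeric",
    lowInputFraction = "numeric",
    cumulativeBins = "logical"
  )
)

setValidity("EnrichmentConfig", function(object) {
  msg <- character()
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  t <- object@binThresholds
  if (length(t) < 1L || any(diff(t) <= 0))
    msg <- c(msg, "binThresholds must be strictly increasing")
  if (object@step < 1L || object@window < object@step)
    msg <- c(msg, "need window >= step >= 1")
  if (object@lowInputFraction < 0)
    msg <- c(msg, "lowInputFraction must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ClassifierConfig: parameters of positional intergenic classification
#'
#' @slot dMax integer; maximum summit-to-gene-end distance (bp) for the
#'   summit to "address" a flank (default 300).
#' @slot bothFlankLen integer; regions at or below this length address both
#'   present flanks regardless of summit position (default 2 * dMax).
#'
#' @seealso [classifierConfig()], [classifyIntergenic()]
#' @export
setClass("ClassifierConfig",
  slots = c(dMax = "integer", bothFlankLen = "integer")
)

setValidity("ClassifierConfig", function(object) {
  if (object@dMax < 1L) "dMax must be >= 1" else TRUE
})

#' StandardCurve: log-linear qPCR dilution curve
#'
#' Model Cq = intercept + slope * log10(percent input). The intercept is the
#' Cq expected at 1\% input (log10 = 0). Amplification efficiency is
#' 10^(-1/slope) - 1, equal to 1 (100\%) at slope -1/log10(2) ~ -3.32.
#'
#' @slot slope numeric (Cq per log10 percent; negative for valid curves).
#' @slot intercept numeric (Cq at 1\% input).
#' @slot r2 numeric, coefficient of determination of the fit.
#' @slot efficiency numeric, 10^(-1/slope) - 1.
#' @slot valid logical; FALSE when the slope is non-negative.
#' @slot points data.frame of the fitted (percent, cq) points.
#'
#' @seealso [fitStandardCurve()], [percentInput()]
#' @export
setClass("StandardCurve",
  slots = c(
    slope = "numeric", intercept = "numeric", r2 = "numeric",
    efficiency = "numeric", valid = "logical", points = "data.frame"
  )
)

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Bundles every knob of the synthetic genome, coverage, qPCR and
#' peptide-array generators. Defaults emulate the analysed study: a
#' gene-dense annotation (gene length log-normal, median 1.5 kb; intergenic
#' gaps median 400 bp), expression tiers at 9\%/29\% high/moderate, planted
#' region-level fold enrichments in the 2-13x range on Poisson coverage at
#' base depth 30 per bp, a 3-point log-linear qPCR standard curve, and
#' peptide-array affinities led by di-acetylated H3 K9ac+K14ac.
#'
#' @seealso [simulationConfig()], [simulateGenome()], [simulateTracks()]
#' @export
setClass("SimulationConfig",
  slots = c(
    seed = "integer",
    nGenes = "integer",
    nChroms = "integer",
    geneLengthMeanlog = "numeric",
    geneLengthSdlog = "numeric",
    gapMeanlog = "numeric",
    gapSdlog = "numeric",
    qHigh = "numeric",
    qMod = "numeric",
    noDataFraction = "numeric",
    rho = "numeric",
    feRange = "numeric",
    genicEnrichedFraction = "numeric",
    plantedClassCounts = "integer",
    compositePromoterOrf = "integer",
    compositeOrfTerminator = "integer",
    lambda = "numeric",
    dispersion = "numericOrNULL",
    intergenicRegionFeRange = "numeric",
    peakWidth = "integer",
    qpcrIntercept = "numeric",
    qpcrSlope = "numeric",
    qpcrSigma = "numeric",
    nTagged = "integer",
    nUntagged = "integer",
    taggedPercent = "numeric",
    untaggedPercent = "numeric",
    arrayNoiseSd = "numeric",
    arrayReplicates = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 2L * object@nChroms)
    msg <- c(msg, "need at least two genes per chromosome")
  if (object@qHigh <= 0 || object@qMod <= 0 ||
      object@qHigh + object@qMod >= 1)
    msg <- c(msg, "tier fractions must satisfy 0 < qHigh, qMod, qHigh + qMod < 1")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
  if (length(object@feRange) != 2L || diff(object@feRange) < 0)
    msg <- c(msg, "feRange must be an increasing pair")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  cls <- c("PROMOTER_SINGLE", "TERMINATOR_SINGLE", "BIDIRECTIONAL_PROMOTER",
           "SHARED_TERMINATOR", "PROMOTER_TERMINATOR_OVERLAP")
  if (!all(cls %in% names(object@plantedClassCounts)))
    msg <- c(msg, "plantedClassCounts must name all five intergenic classes")
  if (length(msg)) msg else TRUE
})
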