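#' @rdname GenomePartition-class
#' @param object,x a \code{GenomePartition}
#' @export
setGeneric("genicRegions", function(x) standardGeneric("genicRegions"))

#' @rdname GenomePartition-class
#' @export
setGeneric("intergenicRegions",
           function(x) standardGeneric("intergenicRegions"))

#' @rdname GenomePartition-class
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomePartition-class
#' @export
setGeneric("geneCatalog", function(x) standardGeneric("geneCatalog"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("totalSignal", function(x) standardGeneric("totalSignal"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackCoverage", function(x) standardGeneric("trackCoverage"))

#' @export
#' @describeIn GenomePartition-class merged genic spans
setMethod("genicRegions", "GenomePartition", function(x) x@genic)

#' @export
#' @describeIn GenomePartition-class intergenic regions with flank metadata
setMethod("intergenicRegions", "GenomePartition", function(x) x@intergenic)

#' @export
#' @describeIn GenomePartition-class named chromosome-length vector
setMethod("chromSizes", "GenomePartition", function(x) x@chromSizes)

#' @export
#' @describeIn GenomePartition-class the input gene models
setMethod("geneCatalog", "GenomePartition", function(x) x@genes)

#' @export
#' @describeIn CoverageTrack-class per-base depth as an \code{RleList}
setMethod("trackCoverage", "CoverageTrack", function(x) x@cov)

#' @export
#' @describeIn CoverageTrack-class sum of all depth values
setMethod("totalSignal", "CoverageTrack", function(x) x@totalSignal)

setMethod("show", "GenomePartition", function(object) {
  cat("GenomePartition:", length(object@chromSizes), "chromosome(s),",
      length(object@genes), "gene(s)\n")
  cat("  genic spans:     ", length(object@genic), "\n", sep = "")
  ig <- object@intergenic
  cat("  intergenic:      ", length(ig),
      sprintf(" (%d edge)", sum(mcols(ig)$edge)), "\n", sep = "")
  cat("  genome length:   ", sum(as.numeric(object@chromSizes)), " bp\n",
      sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", length(object@cov), "chromosome(s), total signal",
      format(object@totalSignal, big.mark = ","), "\n")
})

setMethod("show", "EnrichmentConfig", function(object) {
  cat("EnrichmentConfig: pseudocount=", object@pseudocount,
      ", bins=[", paste(object@binThresholds, collapse = ","),
      "], window=", object@window, ", step=", object@step,
      ", minWindowIpDepth=", object@minWindowIpDepth,
      ", lowInputFraction=", object@lowInputFraction,
      ", cumulativeBins=", object@cumulativeBins, "\n", sep = "")
})

setMethod("show", "ClassifierConfig", function(object) {
  cat("ClassifierConfig: dMax=", object@dMax,
      " bp, bothFlankLen=", object@bothFlankLen, " bp\n", sep = "")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: Cq = %.4f %+.4f * log10(%%input); R2 = %.4f; efficiency = %.1f%%%s\n",
    object@intercept, object@slope, object@r2, 100 * object@efficiency,
    if (object@valid) "" else " [INVALID: non-negative slope]"))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed=", object@seed, ", ", object@nGenes,
      " genes on ", object@nChroms, " chromosome(s), lambda=", object@lambda,
      ", rho=", object@rho, "\n", sep = "")
})
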