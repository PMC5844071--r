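.padCoverage <- function(cov, chromSizes) {
  out <- lapply(names(chromSizes), function(chrom) {
    len <- chromSizes[[chrom]]
    if (chrom %in% names(cov)) {
      r <- cov[[chrom]]
      if (length(r) > len)
        stop("coverage on ", chrom, " exceeds chromosome length")
      if (length(r) < len) r <- c(r, Rle(0, len - length(r)))
      r
    } else {
      Rle(0, len)
    }
  })
  names(out) <- names(chromSizes)
  methods::as(out, "SimpleRleList")
}

#' Construct a CoverageTrack
#'
#' @param cov an \code{RleList} of per-base depths, or a \code{GRanges} with
#'   a \code{score} column (interpreted as constant depth over each range).
#' @param chromSizes named chromosome-length vector; chromosomes absent from
#'   \code{cov} are filled with zeros.
#' @return A [CoverageTrack-class].
#' @export
coverageTrack <- function(cov, chromSizes) {
  if (methods::is(cov, "GRanges")) {
    w <- if ("score" %in% names(mcols(cov))) mcols(cov)$score else 1
    cov <- coverage(cov, weight = w)
  }
  cov <- .padCoverage(cov, chromSizes)
  total <- sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) *
                                             runLength(r)), numeric(1)))
  new("CoverageTrack", cov = cov, totalSignal = total)
}

#' @importFrom S4Vectors runLength
NULL

#' Read a coverage track from a 4-column bedGraph
#'
#' @param path bedGraph file (0-based half-open, as written by standard
#'   tools; converted on import).
#' @param chromSizes named chromosome-length vector.
#' @return A [CoverageTrack-class].
#' @export
coverageFromBedGraph <- function(path, chromSizes) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  unknown <- setdiff(as.character(seqnames(gr)), names(chromSizes))
  if (length(unknown))
    stop("bedGraph chromosome not in chrom sizes: ",
         paste(unknown, collapse = ", "))
  coverageTrack(gr, chromSizes)
}

#' Read a coverage track from read intervals in BED
#'
#' Each BED interval contributes depth 1 over its span (a pseudo-read).
#'
#' @inheritParams coverageFromBedGraph
#' @param extend optional fragment-extension length in bp; reads are extended
#'   to this length in their strand direction before piling up.
#' @export
coverageFromBed <- function(path, chromSizes, extend = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(extend))
    gr <- GenomicRanges::resize(gr, width = extend, fix = "start")
  gr <- GenomicRanges::trim(GRanges(seqnames(gr), ranges(gr),
    seqlengths = chromSizes[intersect(names(chromSizes),
                                      unique(as.character(seqnames(gr))))]))
  mcols(gr)$score <- NULL
  coverageTrack(coverage(gr), chromSizes)
}

#' Read a coverage track from a BAM file
#'
#' Per-base depth counts read-spanning bases (no fragment extension unless
#' \code{extend} is given). Requires the Rsamtools package.
#'
#' @inheritParams coverageFromBed
#' @export
coverageFromBam <- function(path, chromSizes, extend = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("coverageFromBam requires the Rsamtools package")
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(b$pos)
  gr <- GRanges(as.character(b$rname)[keep],
                IRanges(b$pos[keep], width = b$qwidth[keep]),
                strand = b$strand[keep])
  if (!is.null(extend))
    gr <- GenomicRanges::resize(gr, width = extend, fix = "start")
  coverageTrack(coverage(gr), chromSizes)
}

#' Sum per-base depth over regions
#'
#' @param track a [CoverageTrack-class].
#' @param regions a \code{GRanges}, or a single region given as
#'   \code{list(chrom=, start=, end=)}.
#' @return Numeric vector of depth sums, one per region.
#' @export
regionSignal <- function(track, regions) {
  if (is.list(regions) && !methods::is(regions, "GRanges"))
    regions <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
  cov <- trackCoverage(track)
  chroms <- as.character(seqnames(regions))
  unknown <- setdiff(chroms, names(cov))
  if (length(unknown))
    stop("region on unknown chromosome: ", paste(unknown, collapse = ", "))
  out <- numeric(length(regions))
  for (chrom in unique(chroms)) {
    i <- which(chroms == chrom)
    r <- cov[[chrom]]
    if (any(start(regions)[i] < 1L) || any(end(regions)[i] > length(r)))
      stop("region off chromosome ", chrom)
    out[i] <- viewSums(Views(r, start(regions)[i], end(regions)[i]))
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  gr <- methods::as(trackCoverage(track), "GRanges")
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
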