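#' Read a two-column chromosome-size table
#'
#' @param path TSV with columns: chromosome name, length (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom))
    stop("duplicated chromosome name in ", path)
  if (any(df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Write a chromosome-size table
#' @param chromSizes named integer vector.
#' @param path output path.
#' @export
writeChromSizes <- function(chromSizes, path) {
  utils::write.table(
    data.frame(chrom = names(chromSizes), length = as.integer(chromSizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## light pre-scan so malformed records are reported with their line number;
## parsing proper is rtracklayer's job
.scanMalformed <- function(path, format) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "gff3" && length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e)
        stop("malformed coordinates (start > end) at line ", i, " of ", path)
    } else if (format == "bed" && length(f) >= 3) {
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (!is.na(s) && !is.na(e) && s >= e)
        stop("malformed coordinates (start >= end) at line ", i, " of ", path)
    }
  }
  invisible(NULL)
}

#' Read gene models from GFF3 or BED
#'
#' Coordinates are converted to the internal 1-based closed convention used
#' throughout the package (GFF3 is native; BED's 0-based half-open intervals
#' are shifted on import by rtracklayer).
#'
#' @param path annotation file.
#' @param format "auto" (by extension), "gff3" or "bed".
#' @param featureType GFF3 \code{type} value selecting gene rows
#'   (default "gene"); ignored for BED.
#' @param chromSizes optional named length vector; when supplied, records on
#'   unknown chromosomes or extending beyond a chromosome end are rejected.
#' @return \code{GRanges} sorted by (chrom, start) with metadata columns
#'   \code{gene_id} and \code{description}.
#' @export
readGenes <- function(path, format = c("auto", "gff3", "bed"),
                      featureType = "gene", chromSizes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  .scanMalformed(path, format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    if ("type" %in% names(mcols(gr)))
      gr <- gr[as.character(mcols(gr)$type) == featureType]
    ids <- if ("ID" %in% names(mcols(gr))) as.character(mcols(gr)$ID)
           else as.character(mcols(gr)$Name)
    desc <- if ("description" %in% names(mcols(gr)))
      as.character(mcols(gr)$description)
    else if ("Name" %in% names(mcols(gr))) as.character(mcols(gr)$Name)
    else NA_character_
  } else {
    ids <- as.character(mcols(gr)$name)
    desc <- NA_character_
  }
  if (any(is.na(ids)) || !length(gr))
    stop("every gene record needs an identifier (GFF3 ID or BED name)")
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  st <- as.character(strand(gr))
  if (any(!st %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!is.null(chromSizes)) {
    unknown <- setdiff(as.character(seqnames(gr)), names(chromSizes))
    if (length(unknown))
      stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    if (any(end(gr) > chromSizes[as.character(seqnames(gr))]))
      stop("gene extends beyond chromosome length")
  }
  mcols(gr) <- DataFrame(gene_id = ids, description = desc)
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  gr
}

#' Write gene models
#'
#' @param genes \code{GRanges} with a \code{gene_id} column.
#' @param path output path.
#' @rdname writeGenes
#' @export
writeGenesGff3 <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(
    source = "chipOccupancy", type = "gene",
    ID = mcols(genes)$gene_id, Name = mcols(genes)$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGenes
#' @export
writeGenesBed <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(name = mcols(genes)$gene_id, score = 0L)
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Partition a genome into genic and intergenic regions
#'
#' Overlapping or bookended gene models are merged into single genic spans
#' (member ids retained); the per-chromosome complement of the genic spans
#' becomes the intergenic regions. Internal gaps carry both flanking genes
#' (the nearest gene on each side); gaps at chromosome ends carry one flank
#' and are flagged \code{edge}. Together, genic and intergenic spans tile
#' each chromosome exactly (before the \code{minIntergenicLength} filter).
#'
#' @param genes \code{GRanges} from [readGenes()].
#' @param chromSizes named length vector covering all gene chromosomes.
#' @param minIntergenicLength gaps shorter than this are dropped (default 1,
#'   i.e. keep all).
#' @return A [GenomePartition-class] object.
#' @export
partitionGenome <- function(genes, chromSizes, minIntergenicLength = 1L) {
  chromSizes <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  gchrom <- as.character(seqnames(genes))
  unknown <- setdiff(gchrom, names(chromSizes))
  if (length(unknown))
    stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  if (any(end(genes) > chromSizes[gchrom]))
    stop("gene extends beyond chromosome length: ",
         paste(mcols(genes)$gene_id[end(genes) > chromSizes[gchrom]],
               collapse = ", "))

  genicL <- list(); interL <- list()
  for (chrom in names(chromSizes)) {
    len <- chromSizes[[chrom]]
    g <- genes[gchrom == chrom]
    if (!length(g)) next  # chromosome with no genes: no regions to report
    g <- g[order(start(g), end(g))]
    merged <- reduce(ranges(g))
    memb <- lapply(seq_along(merged), function(k) {
      hit <- start(g) <= end(merged)[k] & end(g) >= start(merged)[k]
      g[hit]
    })
    ids <- vapply(memb, function(m)
      paste(mcols(m)$gene_id, collapse = "|"), character(1))
    genicL[[chrom]] <- GRanges(chrom, merged,
                               region_id = ids,
                               member_ids = ids)
    ## gaps: complement of merged spans within [1, len]
    bounds <- c(0L, as.vector(rbind(start(merged), end(merged))), len + 1L)
    nGap <- length(merged) + 1L
    gs <- integer(0); ge <- integer(0)
    lg <- character(0); ls <- character(0)
    rg <- character(0); rs <- character(0); edge <- logical(0)
    idx <- 0L
    for (k in seq_len(nGap)) {
      s <- bounds[2L * k - 1L] + 1L
      e <- bounds[2L * k] - 1L
      if (e < s) next
      leftSpan <- if (k > 1L) memb[[k - 1L]] else NULL
      rightSpan <- if (k <= length(merged)) memb[[k]] else NULL
      pickLeft <- function(m) {  # nearest gene on the left: greatest end
        o <- order(-end(m), -start(m), mcols(m)$gene_id)
        m[o[1L]]
      }
      pickRight <- function(m) {  # nearest gene on the right: least start
        o <- order(start(m), end(m), mcols(m)$gene_id)
        m[o[1L]]
      }
      gs <- c(gs, s); ge <- c(ge, e)
      if (is.null(leftSpan)) {
        lg <- c(lg, NA_character_); ls <- c(ls, NA_character_)
      } else {
        lf <- pickLeft(leftSpan)
        lg <- c(lg, mcols(lf)$gene_id); ls <- c(ls, as.character(strand(lf)))
      }
      if (is.null(rightSpan)) {
        rg <- c(rg, NA_character_); rs <- c(rs, NA_character_)
      } else {
        rf <- pickRight(rightSpan)
        rg <- c(rg, mcols(rf)$gene_id); rs <- c(rs, as.character(strand(rf)))
      }
      edge <- c(edge, is.null(leftSpan) || is.null(rightSpan))
    }
    if (length(gs)) {
      keep <- (ge - gs + 1L) >= minIntergenicLength
      if (any(keep)) {
        n <- sum(keep)
        interL[[chrom]] <- GRanges(
          chrom, IRanges(gs[keep], ge[keep]),
          region_id = sprintf("IG_%s_%04d", chrom, seq_len(n)),
          left_gene = lg[keep], left_strand = ls[keep],
          right_gene = rg[keep], right_strand = rs[keep],
          edge = edge[keep])
      }
    }
  }
  emptyGenic <- GRanges(region_id = character(0), member_ids = character(0))
  emptyInter <- GRanges(region_id = character(0),
                        left_gene = character(0), left_strand = character(0),
                        right_gene = character(0), right_strand = character(0),
                        edge = logical(0))
  genic <- if (length(genicL))
    suppressWarnings(do.call(c, unname(genicL))) else emptyGenic
  inter <- if (length(interL))
    suppressWarnings(do.call(c, unname(interL))) else emptyInter
  new("GenomePartition", genes = genes, genic = genic, intergenic = inter,
      chromSizes = chromSizes,
      minIntergenicLength = as.integer(minIntergenicLength))
}

#' Tabulate a partition as a report data frame
#'
#' Coordinates are 1-based inclusive, matching genome-browser display.
#'
#' @param partition a [GenomePartition-class].
#' @return data.frame with one row per region.
#' @export
partitionReport <- function(partition) {
  g <- genicRegions(partition)
  ig <- intergenicRegions(partition)
  rbindDf <- function(a, b) rbind(a, b)
  dfG <- data.frame(
    region_id = mcols(g)$region_id,
    chrom = as.character(seqnames(g)), start = start(g), end = end(g),
    type = rep("ORF", length(g)),
    left_gene = NA_character_, left_strand = NA_character_,
    right_gene = NA_character_, right_strand = NA_character_,
    edge = NA, stringsAsFactors = FALSE)
  dfI <- data.frame(
    region_id = mcols(ig)$region_id,
    chrom = as.character(seqnames(ig)), start = start(ig), end = end(ig),
    type = rep("INTERGENIC", length(ig)),
    left_gene = mcols(ig)$left_gene, left_strand = mcols(ig)$left_strand,
    right_gene = mcols(ig)$right_gene, right_strand = mcols(ig)$right_strand,
    edge = mcols(ig)$edge, stringsAsFactors = FALSE)
  out <- rbindDf(dfG, dfI)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname partitionReport
#' @param path output TSV path.
#' @export
writePartitionReport <- function(partition, path) {
  utils::write.table(partitionReport(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
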