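INTERGENIC_CLASSES <- c("PROMOTER_SINGLE", "TERMINATOR_SINGLE",
                        "PROMOTER_TERMINATOR_OVERLAP",
                        "BIDIRECTIONAL_PROMOTER", "SHARED_TERMINATOR",
                        "UNCLASSIFIED")

#' Configure the positional intergenic classifier
#'
#' @param dMax maximum summit-to-gene-end distance (bp) for the summit to
#'   "address" a flanking gene (default 300).
#' @param bothFlankLen regions at or below this length (bp) address both
#'   present flanks regardless of summit position (default \code{2 * dMax}).
#' @return A [ClassifierConfig-class].
#' @export
classifierConfig <- function(dMax = 300L, bothFlankLen = 2L * dMax) {
  new("ClassifierConfig", dMax = as.integer(dMax),
      bothFlankLen = as.integer(bothFlankLen))
}

#' Flank geometry of an intergenic region
#'
#' A left-flank gene on the + strand abuts the region with its 3' end; on
#' the - strand with its 5' end. The right flank is mirrored (+ gives the 5'
#' end, - the 3' end). Distances run from the summit to the abutting gene
#' boundary.
#'
#' @param region one row of [intergenicRegions()] metadata as a list or a
#'   length-1 GRanges with the flank columns.
#' @param summit summit position (1-based, inside the region).
#' @return list with per-flank gene, strand, end ("5p"/"3p") and distance.
#' @export
flankGeometry <- function(region, summit) {
  if (methods::is(region, "GRanges")) {
    m <- as.list(mcols(region))
    region <- list(start = start(region), end = end(region),
                   left_gene = m$left_gene, left_strand = m$left_strand,
                   right_gene = m$right_gene, right_strand = m$right_strand)
  }
  if (summit < region$start || summit > region$end)
    stop("summit outside region")
  left <- NULL; right <- NULL
  if (!is.na(region$left_gene)) {
    left <- list(gene = region$left_gene, strand = region$left_strand,
                 end = if (region$left_strand == "+") "3p" else "5p",
                 distance = summit - (region$start - 1L))
  }
  if (!is.na(region$right_gene)) {
    right <- list(gene = region$right_gene, strand = region$right_strand,
                  end = if (region$right_strand == "+") "5p" else "3p",
                  distance = (region$end + 1L) - summit)
  }
  list(left = left, right = right,
       width = region$end - region$start + 1L)
}

#' Classify one enriched intergenic region by flank orientation
#'
#' A flank is addressed when the summit lies within \code{dMax} bp of the
#' abutting gene end, or unconditionally when the region is no longer than
#' \code{bothFlankLen}. Two addressed 5' ends give a bidirectional promoter;
#' two 3' ends a shared terminator; one of each a promoter-terminator
#' overlap; a single addressed flank gives the single promoter or terminator
#' class; no addressed flank is UNCLASSIFIED. Edge regions (one flank) are
#' classified on their single flank.
#'
#' @param region as in [flankGeometry()].
#' @param summit summit position inside the region.
#' @param config a [ClassifierConfig-class].
#' @return list(class, promoter_genes, terminator_genes, geometry).
#' @export
classifyIntergenic <- function(region, summit,
                               config = classifierConfig()) {
  g <- flankGeometry(region, summit)
  addr <- function(fl) !is.null(fl) &&
    (fl$distance <= config@dMax || g$width <= config@bothFlankLen)
  aL <- addr(g$left); aR <- addr(g$right)
  ends <- c(if (aL) g$left$end, if (aR) g$right$end)
  genes <- c(if (aL) g$left$gene, if (aR) g$right$gene)
  cls <- if (length(ends) == 2L) {
    if (all(ends == "5p")) "BIDIRECTIONAL_PROMOTER"
    else if (all(ends == "3p")) "SHARED_TERMINATOR"
    else "PROMOTER_TERMINATOR_OVERLAP"
  } else if (length(ends) == 1L) {
    if (ends == "5p") "PROMOTER_SINGLE" else "TERMINATOR_SINGLE"
  } else "UNCLASSIFIED"
  list(class = cls,
       promoter_genes = genes[ends == "5p"],
       terminator_genes = genes[ends == "3p"],
       geometry = g)
}

#' Classify all enriched intergenic regions
#'
#' @param table enrichment table rows (INTERGENIC type), already filtered to
#'   the chosen fold-enrichment threshold. Rows without a summit (no strong
#'   peak) fall back to the region midpoint and are flagged.
#' @param partition the [GenomePartition-class] the table derives from.
#' @param config a [ClassifierConfig-class].
#' @return list(assignments = data.frame(region_id, class, promoter_genes,
#'   terminator_genes, summit, midpoint_fallback, dist_left, dist_right),
#'   counts = named integer vector over the five classes + UNCLASSIFIED).
#' @export
classifyAll <- function(table, partition, config = classifierConfig()) {
  ig <- intergenicRegions(partition)
  table <- table[table$type == "INTERGENIC", , drop = FALSE]
  idx <- match(table$region_id, mcols(ig)$region_id)
  if (anyNA(idx))
    stop("region id absent from partition: ",
         paste(table$region_id[is.na(idx)], collapse = ", "))
  n <- nrow(table)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- ig[idx[i]]
    fallback <- is.na(table$summit[i])
    summit <- if (fallback) as.integer((start(r) + end(r)) %/% 2L)
              else table$summit[i]
    cl <- classifyIntergenic(r, summit, config)
    rows[[i]] <- data.frame(
      region_id = table$region_id[i], class = cl$class,
      promoter_genes = paste(cl$promoter_genes, collapse = ","),
      terminator_genes = paste(cl$terminator_genes, collapse = ","),
      summit = summit, midpoint_fallback = fallback,
      dist_left = if (is.null(cl$geometry$left)) NA_integer_
                  else cl$geometry$left$distance,
      dist_right = if (is.null(cl$geometry$right)) NA_integer_
                   else cl$geometry$right$distance,
      stringsAsFactors = FALSE)
  }
  assignments <- if (n) do.call(rbind, rows) else data.frame(
    region_id = character(0), class = character(0),
    promoter_genes = character(0), terminator_genes = character(0),
    summit = integer(0), midpoint_fallback = logical(0),
    dist_left = integer(0), dist_right = integer(0))
  counts <- table(factor(assignments$class, levels = INTERGENIC_CLASSES))
  list(assignments = assignments,
       counts = stats::setNames(as.integer(counts), INTERGENIC_CLASSES))
}

#' Combine enriched ORFs with their classified flanking regions
#'
#' An enriched ORF whose own promoter-side intergenic region is classified
#' PROMOTER_SINGLE or BIDIRECTIONAL_PROMOTER (addressing that ORF) falls in
#' the promoter+ORF category; analogously TERMINATOR_SINGLE or
#' SHARED_TERMINATOR give the ORF+terminator category. An ORF may appear in
#' both.
#'
#' @param enrichedOrfIds gene ids of enriched ORFs (same threshold as the
#'   classified table).
#' @param assignments the \code{assignments} element of [classifyAll()].
#' @return list(promoter_plus_orf, orf_plus_terminator) of sorted gene ids.
#' @export
combineOrfFlanks <- function(enrichedOrfIds, assignments) {
  splitGenes <- function(x) unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE),
                                   use.names = FALSE)
  promClasses <- c("PROMOTER_SINGLE", "BIDIRECTIONAL_PROMOTER")
  termClasses <- c("TERMINATOR_SINGLE", "SHARED_TERMINATOR")
  promGenes <- splitGenes(
    assignments$promoter_genes[assignments$class %in% promClasses])
  termGenes <- splitGenes(
    assignments$terminator_genes[assignments$class %in% termClasses])
  list(promoter_plus_orf = sort(intersect(enrichedOrfIds, promGenes)),
       orf_plus_terminator = sort(intersect(enrichedOrfIds, termGenes)))
}

#' Write intergenic class assignments and summary
#'
#' @param classified output of [classifyAll()].
#' @param path output TSV path for assignments; the summary goes to
#'   \code{paste0(path, ".summary")} unless \code{summaryPath} is given.
#' @param config the [ClassifierConfig-class] used (recorded in the header).
#' @param summaryPath optional summary TSV path.
#' @export
writeClassReport <- function(classified, path,
                             config = classifierConfig(),
                             summaryPath = paste0(path, ".summary")) {
  con <- file(path, "w")
  writeLines(sprintf("# chipOccupancy %s | dMax=%d | bothFlankLen=%d",
                     as.character(utils::packageVersion("chipOccupancy")),
                     config@dMax, config@bothFlankLen), con)
  utils::write.table(classified$assignments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  utils::write.table(
    data.frame(class = names(classified$counts),
               count = classified$counts, row.names = NULL),
    summaryPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
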