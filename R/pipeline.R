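.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full occupancy pipeline
#'
#' Orchestrates partition, enrichment ranking, strong-peak filtering,
#' expression-tier cross-tabulation, intergenic classification, combined
#' promoter+ORF / ORF+terminator categories, optional over-representation
#' analysis, and the optional qPCR/array assay computations, writing each
#' report as TSV into \code{outDir}. A manifest records every tunable
#' parameter and the md5 checksum of every input, so reports are
#' reproducible from manifest + inputs; running twice on identical inputs
#' yields byte-identical reports. A missing expression table downgrades
#' gracefully: occupancy reports are still produced and tier reports are
#' skipped with a warning.
#'
#' @param annotation GFF3 (or BED) gene annotation path.
#' @param chromSizes two-column chrom.sizes path.
#' @param ip,input bedGraph coverage paths.
#' @param outDir output directory.
#' @param expression optional expression TSV (gene_id, value).
#' @param termMap optional gene-to-term TSV or GMT for over-representation.
#' @param qpcr optional qPCR TSV (see [readQpcr()]).
#' @param array optional peptide-array TSV (see [readPeptideArray()]).
#' @param histoneFasta optional histone FASTA for conservation flags.
#' @param enrichConfig an [EnrichmentConfig-class].
#' @param classConfig a [ClassifierConfig-class].
#' @param qHigh,qMod expression-tier fractions.
#' @param thresholds report fold-enrichment thresholds; the first defines
#'   the occupied set (with strong peaks), the last the classified set.
#' @param minIntergenicLength passed to [partitionGenome()].
#' @return invisibly, a list of the computed tables.
#' @export
runOccupancy <- function(annotation, chromSizes, ip, input, outDir,
                         expression = NULL, termMap = NULL, qpcr = NULL,
                         array = NULL, histoneFasta = NULL,
                         enrichConfig = enrichmentConfig(),
                         classConfig = classifierConfig(),
                         qHigh = 0.09, qMod = 0.29,
                         thresholds = c(2, 4),
                         minIntergenicLength = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  out <- list()

  cs <- .stage("chrom_sizes", readChromSizes(chromSizes))
  genes <- .stage("annotation", readGenes(annotation, chromSizes = cs))
  partition <- .stage("partition",
                      partitionGenome(genes, cs, minIntergenicLength))
  writePartitionReport(partition, p("partition.tsv"))
  out$partition <- partition

  ipTrack <- .stage("coverage", coverageFromBedGraph(ip, cs))
  inputTrack <- .stage("coverage", coverageFromBedGraph(input, cs))
  enrichTab <- .stage("enrichment",
                      enrichRegions(ipTrack, inputTrack, partition,
                                    enrichConfig))
  writeEnrichmentReport(enrichTab, p("enrichment_all.tsv"), enrichConfig)
  out$enrichment <- enrichTab
  for (t in thresholds) {
    for (ty in c("ORF", "INTERGENIC")) {
      writeEnrichmentReport(
        filterEnriched(enrichTab, t, strongOnly = FALSE, type = ty),
        p(sprintf("enriched_%s_ge%g.tsv", tolower(ty), t)), enrichConfig)
      writeEnrichmentReport(
        filterEnriched(enrichTab, t, strongOnly = TRUE, type = ty),
        p(sprintf("enriched_%s_ge%g_strong.tsv", tolower(ty), t)),
        enrichConfig)
    }
  }

  tLow <- thresholds[1]; tHigh <- thresholds[length(thresholds)]
  occupied <- filterEnriched(enrichTab, tLow, strongOnly = TRUE,
                             type = "ORF")
  occupiedIds <- enrichedGeneIds(occupied)

  tiers <- NULL
  if (!is.null(expression) && file.exists(expression)) {
    exprTab <- .stage("expression", readExpression(expression))
    tiers <- .stage("tiers",
                    assignTiers(exprTab,
                                universe = mcols(genes)$gene_id,
                                qHigh = qHigh, qMod = qMod))
    crosstab <- .stage("crosstab", crosstabOccupancy(occupiedIds, tiers))
    utils::write.table(crosstab, p("tier_crosstab.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    trend <- .stage("trend", tierTrendByBin(enrichTab, tiers, enrichConfig))
    utils::write.table(trend$per_bin, p("tier_trend_per_bin.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(trend$cumulative, p("tier_trend_cumulative.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$tiers <- tiers; out$crosstab <- crosstab; out$trend <- trend
  } else {
    warning("no expression table; tier reports skipped")
  }

  classifiedInput <- filterEnriched(enrichTab, tHigh, type = "INTERGENIC")
  classified <- .stage("classify",
                       classifyAll(classifiedInput, partition, classConfig))
  writeClassReport(classified, p("intergenic_classes.tsv"), classConfig,
                   summaryPath = p("intergenic_class_summary.tsv"))
  out$classified <- classified

  enrichedHighIds <- enrichedGeneIds(
    filterEnriched(enrichTab, tHigh, type = "ORF"))
  combined <- .stage("combine",
                     combineOrfFlanks(enrichedHighIds,
                                      classified$assignments))
  writeLines(c(
    paste0("promoter_plus_orf\t",
           paste(combined$promoter_plus_orf, collapse = ",")),
    paste0("orf_plus_terminator\t",
           paste(combined$orf_plus_terminator, collapse = ","))),
    p("combined_categories.tsv"))
  out$combined <- combined

  if (!is.null(termMap) && file.exists(termMap)) {
    tm <- .stage("term_map",
                 if (grepl("\\.gmt$", termMap, ignore.case = TRUE))
                   readGmt(termMap) else readTermMap(termMap))
    ora <- .stage("ora",
                  overrepresentation(enrichedHighIds,
                                     mcols(genes)$gene_id, tm))
    utils::write.table(ora, p("ora.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$ora <- ora
  }

  if (!is.null(qpcr) && file.exists(qpcr)) {
    qres <- .stage("qpcr", analyzeQpcr(readQpcr(qpcr)))
    utils::write.table(qres, p("qpcr_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$qpcr <- qres
  }
  if (!is.null(array) && file.exists(array)) {
    hist <- if (!is.null(histoneFasta)) readHistoneFasta(histoneFasta)
    ares <- .stage("array",
                   rankArray(readPeptideArray(array), topK = Inf,
                             histoneSeqs = hist))
    utils::write.table(ares, p("array_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$array <- ares
  }

  inputs <- c(annotation = annotation, chrom_sizes = chromSizes, ip = ip,
              input = input, expression = expression, term_map = termMap,
              qpcr = qpcr, array = array, histone_fasta = histoneFasta)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("chipOccupancy"))),
    sprintf("pseudocount\t%g", enrichConfig@pseudocount),
    sprintf("bin_thresholds\t%s",
            paste(enrichConfig@binThresholds, collapse = ",")),
    sprintf("window\t%d", enrichConfig@window),
    sprintf("step\t%d", enrichConfig@step),
    sprintf("min_window_ip_depth\t%g", enrichConfig@minWindowIpDepth),
    sprintf("low_input_fraction\t%g", enrichConfig@lowInputFraction),
    sprintf("d_max\t%d", classConfig@dMax),
    sprintf("both_flank_len\t%d", classConfig@bothFlankLen),
    sprintf("q_high\t%g", qHigh), sprintf("q_mod\t%g", qMod),
    sprintf("thresholds\t%s", paste(thresholds, collapse = ",")),
    sprintf("min_intergenic_length\t%d", as.integer(minIntergenicLength)),
    sprintf("input_md5_%s\t%s", names(inputs),
            unname(tools::md5sum(unlist(inputs)))))
  writeLines(manifest, p("manifest.tsv"))
  invisible(out)
}
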