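TIER_LEVELS <- c("HIGH", "MODERATE", "LOW_NO", "NO_DATA")

#' Read a gene-expression table
#'
#' @param path TSV with header columns \code{gene_id} and \code{value} (any
#'   monotone expression score: FPKM, counts, ranks...).
#' @return data.frame(gene_id, value).
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(df)))
    stop("expression table needs columns gene_id and value")
  df[, c("gene_id", "value")]
}

#' Assign quantile expression tiers
#'
#' Genes with data are ranked by descending expression (ties broken stably
#' by gene id); the top \code{ceiling(qHigh * n)} are HIGH, the next
#' \code{ceiling(qMod * n)} MODERATE, the remainder LOW_NO. Genes in the
#' universe but absent from the table are NO_DATA, a first-class tier.
#'
#' @param expression data.frame(gene_id, value) with non-negative values.
#' @param universe character vector of all gene ids (default: the table's
#'   genes).
#' @param qHigh,qMod tier fractions (defaults 0.09 and 0.29).
#' @return data.frame(gene_id, value, rank, tier) over the universe; rank is
#'   NA for NO_DATA genes; tier is a factor with levels HIGH, MODERATE,
#'   LOW_NO, NO_DATA.
#' @export
assignTiers <- function(expression, universe = NULL,
                        qHigh = 0.09, qMod = 0.29) {
  stopifnot(qHigh > 0, qMod > 0, qHigh + qMod < 1)
  if (is.null(universe)) universe <- expression$gene_id
  if (anyDuplicated(expression$gene_id))
    stop("duplicated gene_id in expression table")
  expression <- expression[expression$gene_id %in% universe, , drop = FALSE]
  if (nrow(expression) && any(expression$value < 0))
    stop("negative expression value")
  n <- nrow(expression)
  o <- order(-expression$value, expression$gene_id)
  ranked <- expression[o, , drop = FALSE]
  nHigh <- min(n, ceiling(qHigh * n))
  nMod <- min(n - nHigh, ceiling(qMod * n))
  tier <- rep("LOW_NO", n)
  if (nHigh > 0) tier[seq_len(nHigh)] <- "HIGH"
  if (nMod > 0) tier[nHigh + seq_len(nMod)] <- "MODERATE"
  out <- data.frame(gene_id = universe, value = NA_real_,
                    rank = NA_integer_, tier = "NO_DATA",
                    stringsAsFactors = FALSE)
  idx <- match(ranked$gene_id, out$gene_id)
  out$value[idx] <- ranked$value
  out$rank[idx] <- seq_len(n)
  out$tier[idx] <- tier
  out$tier <- factor(out$tier, levels = TIER_LEVELS)
  out
}

#' Cross-tabulate occupancy against expression tiers
#'
#' Counts and percentages of each tier within the enriched gene set, next to
#' the same breakdown for the whole universe (the background panel).
#'
#' @param enrichedIds gene ids called occupied/enriched; must all be in the
#'   universe.
#' @param tiers output of [assignTiers()].
#' @return data.frame(tier, count_enriched, pct_enriched, count_universe,
#'   pct_universe).
#' @export
crosstabOccupancy <- function(enrichedIds, tiers) {
  enrichedIds <- unique(enrichedIds)
  missing <- setdiff(enrichedIds, tiers$gene_id)
  if (length(missing))
    stop("enriched gene(s) not in universe: ",
         paste(missing, collapse = ", "))
  tierOf <- stats::setNames(tiers$tier, tiers$gene_id)
  encounts <- table(factor(tierOf[enrichedIds], levels = TIER_LEVELS))
  uncounts <- table(factor(tiers$tier, levels = TIER_LEVELS))
  nE <- max(1L, length(enrichedIds)); nU <- max(1L, nrow(tiers))
  data.frame(
    tier = TIER_LEVELS,
    count_enriched = as.integer(encounts),
    pct_enriched = 100 * as.integer(encounts) / nE,
    count_universe = as.integer(uncounts),
    pct_universe = 100 * as.integer(uncounts) / nU,
    stringsAsFactors = FALSE)
}

#' Tier composition per fold-enrichment bin
#'
#' For each fold-enrichment bin of the ORF enrichment table, the fraction of
#' genes in each expression tier. Two layouts are returned: per-bin
#' (half-open intervals) and cumulative (genes at or above each threshold).
#' The monotonicity report asks whether the HIGH fraction is non-decreasing
#' with increasing enrichment; it is judged on the cumulative layout, which
#' matches how ">= t" site counts are usually displayed and is stable when
#' the top interval holds few genes.
#'
#' @param table output of [enrichRegions()], ORF rows (other types are
#'   dropped); genes below the first threshold are not part of the trend.
#' @param tiers output of [assignTiers()].
#' @param config an [EnrichmentConfig-class] (bin thresholds).
#' @return list(per_bin = data.frame, cumulative = data.frame,
#'   high_monotone = logical).
#' @export
tierTrendByBin <- function(table, tiers, config = enrichmentConfig()) {
  orf <- table[table$type == "ORF", , drop = FALSE]
  genes <- .memberGenes(orf$region_id)
  fe <- rep(orf$fold_enrichment, lengths(genes))
  gene <- unlist(genes, use.names = FALSE)
  tierOf <- stats::setNames(as.character(tiers$tier), tiers$gene_id)
  tier <- factor(unname(tierOf[gene]), levels = TIER_LEVELS)
  t <- config@binThresholds
  keep <- fe >= t[1]
  fe <- fe[keep]; tier <- tier[keep]
  binTab <- function(sel, label) {
    tt <- table(tier[sel])
    n <- sum(tt)
    data.frame(bin = label, n = n,
               t(as.matrix(if (n) tt / n else tt * 0)),
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  labs <- .binLabels(t)[-1]
  bins <- as.character(.assignBins(fe, t))
  perBin <- do.call(rbind, lapply(seq_along(t), function(i)
    binTab(bins == labs[i], labs[i])))
  cum <- do.call(rbind, lapply(t, function(x)
    binTab(fe >= x, sprintf(">=%g", x))))
  rownames(perBin) <- rownames(cum) <- NULL
  highFrac <- cum$HIGH[cum$n > 0]
  list(per_bin = perBin, cumulative = cum,
       high_monotone = length(highFrac) <= 1 ||
         all(diff(highFrac) >= -1e-12))
}

## genic region ids are member gene ids joined by "|"
.memberGenes <- function(regionIds) strsplit(regionIds, "|", fixed = TRUE)

#' Gene ids of enriched ORF regions
#'
#' Expands genic region ids (merged spans join member ids with "|") into the
#' underlying gene ids.
#'
#' @param table an enrichment table, already filtered as desired.
#' @return character vector of unique gene ids.
#' @export
enrichedGeneIds <- function(table) {
  unique(unlist(.memberGenes(table$region_id[table$type == "ORF"]),
                use.names = FALSE))
}
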