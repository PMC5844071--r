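#' Read a gene-to-term map from a two-column TSV
#'
#' @param path TSV with header columns \code{gene_id} and \code{term}.
#' @return named list: term -> character vector of gene ids.
#' @export
readTermMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(df)))
    stop("term map needs columns gene_id and term")
  lapply(split(df$gene_id, df$term), unique)
}

#' Read a gene-set collection in GMT format
#'
#' @param path GMT file: term, description, then member genes, tab-separated.
#' @return named list: term -> character vector of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one gene in the query set, the upper-tail
#' hypergeometric probability of observing at least the overlap by drawing
#' the query set from the universe, with Benjamini-Hochberg adjustment
#' across tested terms. Genes without any term annotation stay in the
#' universe by default (conservative).
#'
#' @param geneSet query gene ids (subset of the universe).
#' @param universe all gene ids.
#' @param termMap named list: term -> gene ids (restricted to the universe
#'   internally; empty terms dropped).
#' @param qThreshold q-value threshold recorded in the \code{significant}
#'   column (default 0.05).
#' @param dropUnannotated restrict the universe (and query) to genes with at
#'   least one term (default FALSE).
#' @return data.frame(term, k, n, K, N, p, q, significant) sorted by q then
#'   p; zero rows for an empty query.
#' @export
overrepresentation <- function(geneSet, universe, termMap,
                               qThreshold = 0.05, dropUnannotated = FALSE) {
  geneSet <- unique(geneSet); universe <- unique(universe)
  outside <- setdiff(geneSet, universe)
  if (length(outside))
    stop("gene(s) outside universe: ", paste(outside, collapse = ", "))
  termMap <- lapply(termMap, function(g) intersect(unique(g), universe))
  termMap <- termMap[lengths(termMap) > 0]
  if (dropUnannotated) {
    annotated <- unique(unlist(termMap, use.names = FALSE))
    universe <- intersect(universe, annotated)
    geneSet <- intersect(geneSet, annotated)
  }
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
  if (!length(geneSet) || !length(termMap)) return(empty)
  N <- length(universe); n <- length(geneSet)
  k <- vapply(termMap, function(g) length(intersect(g, geneSet)), integer(1))
  K <- lengths(termMap)
  keep <- k >= 1L
  if (!any(keep)) return(empty)
  k <- k[keep]; K <- K[keep]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(termMap)[keep], k = k, n = n, K = K, N = N,
                    p = p, q = q, significant = q <= qThreshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
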