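#' Read a histone peptide-array intensity table
#'
#' @param path TSV with header columns \code{peptide_id}, \code{histone}
#'   (e.g. "H3"), \code{modifications} (tokens like "K9ac", "S10P",
#'   "R3me2s" joined by "+"), then one column per replicate
#'   (\code{rep1}, \code{rep2}, ...).
#' @return data.frame of spots with replicate columns.
#' @export
readPeptideArray <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("peptide_id", "histone", "modifications")
  if (!all(need %in% names(df)))
    stop("array table needs columns ", paste(need, collapse = ", "))
  if (!any(grepl("^rep[0-9]+$", names(df))))
    stop("array table needs replicate columns rep1, rep2, ...")
  df
}

#' Parse modification tokens
#'
#' "K9ac" parses as residue K, position 9, mark "ac"; "R3me2s" as residue R,
#' position 3, mark "me2s"; unmodified tokens are rejected.
#'
#' @param tokens character vector like \code{c("K9ac", "K14ac")}.
#' @return data.frame(token, residue, position, mark).
#' @export
parseModifications <- function(tokens) {
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Za-z0-9]+)$", tokens))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("cannot parse modification token(s): ",
         paste(tokens[bad], collapse = ", "))
  data.frame(token = tokens,
             residue = vapply(m, `[`, character(1), 2L),
             position = as.integer(vapply(m, `[`, character(1), 3L)),
             mark = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

.flagNonConserved <- function(histone, modifications, histoneSeqs) {
  if (is.null(histoneSeqs) || !nzchar(modifications)) return("")
  if (!histone %in% names(histoneSeqs)) return("")
  seq <- as.character(histoneSeqs[[histone]])
  toks <- parseModifications(strsplit(modifications, "+", fixed = TRUE)[[1]])
  bad <- toks$position > nchar(seq) |
    substring(seq, toks$position, toks$position) != toks$residue
  paste(toks$token[bad], collapse = ",")
}

#' Rank peptide-array spots by mean binding intensity
#'
#' Averages replicate intensities per spot and returns the top spots in
#' descending order (ties broken by peptide id). Raw intensities (outside
#' [0, 1]) are min-max normalized across the whole array first; tables
#' already on a [0, 1] scale pass through unchanged (override with
#' \code{normalize}). When histone sequences are supplied, every modified
#' residue is checked against the corresponding sequence and mismatches are
#' listed in \code{non_conserved} (residues absent from the target species'
#' histone).
#'
#' @param spots data.frame from [readPeptideArray()].
#' @param topK number of rows to return (default 10; \code{Inf} for all).
#' @param histoneSeqs optional named \code{AAStringSet} (or named character
#'   vector) of histone sequences, e.g. from [readHistoneFasta()].
#' @param normalize "auto" (range check), "minmax" or "none".
#' @return data.frame(rank, peptide_id, histone, modifications,
#'   mean_intensity, non_conserved).
#' @export
rankArray <- function(spots, topK = 10, histoneSeqs = NULL,
                      normalize = c("auto", "minmax", "none")) {
  normalize <- match.arg(normalize)
  repCols <- grep("^rep[0-9]+$", names(spots), value = TRUE)
  mat <- as.matrix(spots[, repCols, drop = FALSE])
  if (anyNA(mat)) {
    bad <- spots$peptide_id[apply(mat, 1L, anyNA)]
    stop("missing replicate intensity for spot(s): ",
         paste(bad, collapse = ", "))
  }
  doNorm <- switch(normalize,
                   minmax = TRUE, none = FALSE,
                   auto = min(mat) < 0 || max(mat) > 1)
  if (doNorm) {
    rng <- range(mat)
    mat <- if (diff(rng) == 0) mat * 0 else (mat - rng[1]) / diff(rng)
  }
  means <- rowMeans(mat)
  if (!is.null(histoneSeqs) && !methods::is(histoneSeqs, "character"))
    histoneSeqs <- stats::setNames(as.character(histoneSeqs),
                                   names(histoneSeqs))
  nonCons <- vapply(seq_len(nrow(spots)), function(i)
    .flagNonConserved(spots$histone[i], spots$modifications[i], histoneSeqs),
    character(1))
  o <- order(-means, spots$peptide_id)
  out <- data.frame(
    rank = seq_along(o),
    peptide_id = spots$peptide_id[o], histone = spots$histone[o],
    modifications = spots$modifications[o],
    mean_intensity = means[o], non_conserved = nonCons[o],
    stringsAsFactors = FALSE)
  utils::head(out, topK)
}

#' Read histone sequences from FASTA
#'
#' @param path FASTA of histone protein sequences named H3, H4, H2A, ...
#' @return named character vector of sequences.
#' @export
readHistoneFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  stats::setNames(as.character(seqs), nm)
}
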