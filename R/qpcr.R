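#' Fit a log-linear qPCR standard curve
#'
#' Least-squares fit of Cq = intercept + slope * log10(percent input) on a
#' dilution series (the study design uses three points at 100, 10 and 1% of
#' the input sample). Amplification efficiency is 10^(-1/slope) - 1, 100%
#' at slope -1/log10(2) (about -3.32 cycles per 10-fold dilution). Curves
#' with non-negative slope are flagged invalid.
#'
#' @param percent dilution percentages (> 0, at least 3 distinct).
#' @param cq measured Cq values.
#' @return A [StandardCurve-class].
#' @export
fitStandardCurve <- function(percent, cq) {
  if (length(percent) != length(cq))
    stop("percent and cq lengths differ")
  if (length(percent) < 3L || length(unique(percent)) < 3L)
    stop("need at least 3 distinct dilution points")
  if (any(percent <= 0)) stop("dilution percent must be > 0")
  x <- log10(percent)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ## computed directly: summary.lm warns on exactly collinear dilutions
  ssTot <- sum((cq - mean(cq))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ssTot
  new("StandardCurve", slope = slope, intercept = intercept, r2 = r2,
      efficiency = 10^(-1 / slope) - 1, valid = slope < 0,
      points = data.frame(percent = percent, cq = cq))
}

#' Percent input from a Cq value
#'
#' Inverts the standard curve: 10^((cq - intercept) / slope).
#'
#' @param cq Cq value(s).
#' @param curve a valid [StandardCurve-class].
#' @return percent-input value(s).
#' @export
percentInput <- function(cq, curve) {
  if (!curve@valid)
    stop("standard curve is invalid (non-negative slope)")
  10^((cq - curve@intercept) / curve@slope)
}

#' Compare tagged and untagged ChIP-qPCR groups
#'
#' Per-replicate fold enrichment is the percent-input value divided by 100
#' (the input sample itself reads 100% by the curve's construction). Group
#' means and standard errors (sd/sqrt(n)) are reported with a two-sided
#' two-sample t test between the groups, Welch by default (the study design
#' has unequal group sizes, 4 tagged vs 3 untagged). When both groups have
#' zero variance and equal means, t = 0 and p = 1 by convention.
#'
#' @param tagged,untagged per-replicate percent-input values (>= 2 each).
#' @param varEqual use Student's pooled-variance t test (default FALSE,
#'   i.e. Welch).
#' @return list(fold_enrichment_tagged, fold_enrichment_untagged,
#'   mean_tagged, mean_untagged, sem_tagged, sem_untagged, fold_change,
#'   t, df, p).
#' @export
qpcrCompare <- function(tagged, untagged, varEqual = FALSE) {
  if (length(tagged) < 2L || length(untagged) < 2L)
    stop("need >= 2 replicates per group")
  feT <- tagged / 100; feU <- untagged / 100
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  degenerate <- stats::sd(feT) == 0 && stats::sd(feU) == 0
  if (degenerate) {
    if (mean(feT) == mean(feU)) {
      t <- 0; df <- length(feT) + length(feU) - 2L; p <- 1
    } else {
      t <- sign(mean(feT) - mean(feU)) * Inf
      df <- length(feT) + length(feU) - 2L; p <- 0
    }
  } else {
    ht <- stats::t.test(feT, feU, var.equal = varEqual,
                        alternative = "two.sided")
    t <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  }
  list(fold_enrichment_tagged = feT, fold_enrichment_untagged = feU,
       mean_tagged = mean(feT), mean_untagged = mean(feU),
       sem_tagged = sem(feT), sem_untagged = sem(feU),
       fold_change = mean(feT) / mean(feU),
       t = t, df = df, p = p)
}

#' Read a ChIP-qPCR measurement table
#'
#' @param path TSV with header columns \code{target}, \code{group}
#'   ("tagged", "untagged" or "dilution"), \code{replicate}, \code{cq} and
#'   \code{percent} (known percent for dilution rows, empty otherwise).
#' @return data.frame of the measurements.
#' @export
readQpcr <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("target", "group", "replicate", "cq", "percent")
  if (!all(need %in% names(df)))
    stop("qPCR table needs columns ", paste(need, collapse = ", "))
  if (any(df$cq <= 0)) stop("Cq values must be > 0")
  df
}

#' Full ChIP-qPCR analysis from raw Cq values
#'
#' Per target: fits the standard curve on the dilution rows, converts IP Cq
#' values to percent input, and compares the tagged and untagged groups.
#'
#' @param measurements data.frame from [readQpcr()].
#' @param varEqual passed to [qpcrCompare()].
#' @return data.frame with one row per target: curve parameters, group
#'   means/SEMs (percent input), fold change, t and p.
#' @export
analyzeQpcr <- function(measurements, varEqual = FALSE) {
  out <- lapply(split(measurements, measurements$target), function(m) {
    dil <- m[m$group == "dilution", , drop = FALSE]
    curve <- fitStandardCurve(dil$percent, dil$cq)
    pct <- function(grp)
      percentInput(m$cq[m$group == grp], curve)
    cmp <- qpcrCompare(pct("tagged"), pct("untagged"), varEqual = varEqual)
    data.frame(target = m$target[1], slope = curve@slope,
               intercept = curve@intercept, r2 = curve@r2,
               efficiency = curve@efficiency,
               mean_tagged = cmp$mean_tagged,
               mean_untagged = cmp$mean_untagged,
               sem_tagged = cmp$sem_tagged, sem_untagged = cmp$sem_untagged,
               fold_change = cmp$fold_change, t = cmp$t, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
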