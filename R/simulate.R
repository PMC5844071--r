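#' Study conditions for the synthetic-data generator
#'
#' Defaults describe the emulated study: a gene-dense genome (gene lengths
#' log-normal with median 1.5 kb; intergenic gaps median 400 bp), expression
#' tiers at 9\%/29\% high/moderate with 14\% of genes lacking expression
#' data, occupancy planted preferentially in highly expressed genes
#' (correlation \code{rho}, default 0.8) with region-level fold enrichments
#' in 2-13x, Poisson coverage at base depth 30 per bp, planted intergenic
#' peaks of every positional class, a 3-point qPCR standard curve
#' (Cq = 26.64 - 3.32 log10(\%input), ~100\% efficiency) with 4 tagged vs 3
#' untagged replicates, and a peptide array led by di-acetylated H3
#' K9ac+K14ac.
#'
#' @param seed integer master seed; a fixed seed gives byte-identical
#'   outputs.
#' @param nGenes,nChroms genome size (defaults 200 genes on 2 chromosomes).
#' @param geneLengthMeanlog,geneLengthSdlog log-normal gene lengths (bp).
#' @param gapMeanlog,gapSdlog log-normal intergenic gap lengths (bp).
#' @param qHigh,qMod,noDataFraction expression-tier fractions.
#' @param rho occupancy-expression correlation in [0, 1].
#' @param feRange planted genic fold-enrichment range (post-normalization).
#' @param genicEnrichedFraction fraction of genes planted as enriched.
#' @param plantedClassCounts named integer vector over the five intergenic
#'   classes.
#' @param compositePromoterOrf,compositeOrfTerminator number of planted
#'   promoter-addressed (resp. terminator-addressed) genes forced into the
#'   enriched ORF set, so combined promoter+ORF / ORF+terminator categories
#'   are non-empty.
#' @param lambda base input depth per bp (Poisson mean).
#' @param dispersion NULL for Poisson; a negative-binomial size parameter
#'   switches on overdispersion.
#' @param intergenicRegionFeRange planted intergenic region-level
#'   fold-enrichment range; the triangular peak height is solved so the
#'   region average hits the drawn target.
#' @param peakWidth triangular intergenic peak width, bp.
#' @param qpcrIntercept,qpcrSlope,qpcrSigma standard-curve parameters and
#'   Cq noise sd.
#' @param nTagged,nUntagged qPCR replicates per group.
#' @param taggedPercent,untaggedPercent true percent-input per target.
#' @param arrayNoiseSd,arrayReplicates peptide-array replicate noise and
#'   count.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nGenes = 200L, nChroms = 2L,
                             geneLengthMeanlog = log(1500),
                             geneLengthSdlog = 0.35,
                             gapMeanlog = log(400), gapSdlog = 0.5,
                             qHigh = 0.09, qMod = 0.29,
                             noDataFraction = 0.14,
                             rho = 0.8, feRange = c(2, 13),
                             genicEnrichedFraction = 0.05,
                             plantedClassCounts = c(
                               PROMOTER_SINGLE = 10L, TERMINATOR_SINGLE = 5L,
                               BIDIRECTIONAL_PROMOTER = 3L,
                               SHARED_TERMINATOR = 3L,
                               PROMOTER_TERMINATOR_OVERLAP = 2L),
                             compositePromoterOrf = 3L,
                             compositeOrfTerminator = 2L,
                             lambda = 30, dispersion = NULL,
                             intergenicRegionFeRange = c(3, 6),
                             peakWidth = 400L,
                             qpcrIntercept = 26.64, qpcrSlope = -3.32,
                             qpcrSigma = 0.1,
                             nTagged = 4L, nUntagged = 3L,
                             taggedPercent = c(8, 6, 5, 1),
                             untaggedPercent = c(1, 1, 1, 1),
                             arrayNoiseSd = 0.02, arrayReplicates = 4L) {
  new("SimulationConfig", seed = as.integer(seed),
      nGenes = as.integer(nGenes), nChroms = as.integer(nChroms),
      geneLengthMeanlog = geneLengthMeanlog,
      geneLengthSdlog = geneLengthSdlog,
      gapMeanlog = gapMeanlog, gapSdlog = gapSdlog,
      qHigh = qHigh, qMod = qMod, noDataFraction = noDataFraction,
      rho = rho, feRange = as.numeric(feRange),
      genicEnrichedFraction = genicEnrichedFraction,
      plantedClassCounts = vapply(plantedClassCounts, as.integer,
                                  integer(1)),
      compositePromoterOrf = as.integer(compositePromoterOrf),
      compositeOrfTerminator = as.integer(compositeOrfTerminator),
      lambda = lambda, dispersion = dispersion,
      intergenicRegionFeRange = as.numeric(intergenicRegionFeRange),
      peakWidth = as.integer(peakWidth),
      qpcrIntercept = qpcrIntercept, qpcrSlope = qpcrSlope,
      qpcrSigma = qpcrSigma,
      nTagged = as.integer(nTagged), nUntagged = as.integer(nUntagged),
      taggedPercent = as.numeric(taggedPercent),
      untaggedPercent = as.numeric(untaggedPercent),
      arrayNoiseSd = arrayNoiseSd,
      arrayReplicates = as.integer(arrayReplicates))
}

.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 131 + 7919 * k)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## class -> planted gap length, flank strands, summit placement rule.
## Single-flank classes use long gaps (one end beyond dMax) with the summit
## 150 bp from the addressed end; both-flank classes use short gaps at or
## below the default bothFlankLen. Placement assumes the default classifier
## (dMax = 300).
.classPlan <- list(
  PROMOTER_SINGLE = list(len = 1200L, left = "+", right = "+",
                         summit = "right"),
  TERMINATOR_SINGLE = list(len = 1200L, left = "+", right = "+",
                           summit = "left"),
  BIDIRECTIONAL_PROMOTER = list(len = 400L, left = "-", right = "+",
                                summit = "mid"),
  SHARED_TERMINATOR = list(len = 400L, left = "+", right = "-",
                           summit = "mid"),
  PROMOTER_TERMINATOR_OVERLAP = list(len = 400L, left = "+", right = "+",
                                     summit = "mid"))

.plannedRoles <- function(class, leftGene, rightGene) {
  switch(class,
         PROMOTER_SINGLE = list(prom = rightGene, term = character(0)),
         TERMINATOR_SINGLE = list(prom = character(0), term = leftGene),
         BIDIRECTIONAL_PROMOTER = list(prom = c(leftGene, rightGene),
                                       term = character(0)),
         SHARED_TERMINATOR = list(prom = character(0),
                                  term = c(leftGene, rightGene)),
         PROMOTER_TERMINATOR_OVERLAP = list(prom = rightGene,
                                            term = leftGene))
}

#' Simulate an annotated genome with expression and planted occupancy
#'
#' Generates gene models on \code{nChroms} chromosomes with all four
#' flanking-strand configurations, plants the configured number of each
#' intergenic positional class (gap geometry and flank strands chosen so the
#' default classifier recovers the class from the planted summit), draws
#' per-gene expression, tiers it, and selects the planted enriched ORF set
#' with probability increasing in expression (strength \code{rho}). Planted
#' genic fold enrichments map expression rank into \code{feRange} so that
#' occupancy strength and expression are positively associated; planted
#' values start slightly above the lowest threshold so region-level calls
#' are not noise-limited at the filter boundary.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{genes} (GRanges), \code{chromSizes},
#'   \code{partition}, \code{expression} (data.frame; genes without data are
#'   absent), \code{tiers}, \code{genicTruth}, \code{intergenicTruth},
#'   \code{composites}.
#' @export
simulateGenome <- function(config) {
  .withSeed(.deriveSeed(config@seed, 1L), {
    nC <- config@nChroms
    perChrom <- rep(config@nGenes %/% nC, nC)
    extra <- config@nGenes %% nC
    if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
    chromNames <- sprintf("chr%d", seq_len(nC))

    ## feasibility: planted gaps occupy odd internal gap indices
    capacity <- sum(ceiling((perChrom - 1L) / 2))
    plan <- rep(names(config@plantedClassCounts), config@plantedClassCounts)
    if (length(plan) > capacity)
      stop("infeasible planted class counts: need ", length(plan),
           " spaced intergenic gaps, only ", capacity, " available")
    planChrom <- rep(seq_len(nC), length.out = length(plan))

    geneL <- list(); interTruthL <- list()
    chromSizes <- integer(0)
    gidx <- 0L
    for (ci in seq_len(nC)) {
      nG <- perChrom[ci]
      chrom <- chromNames[ci]
      classes <- plan[planChrom == ci]
      gapIdx <- seq.int(1L, by = 2L, length.out = length(classes))
      lens <- pmax(300L, as.integer(round(stats::rlnorm(
        nG, config@geneLengthMeanlog, config@geneLengthSdlog))))
      gaps <- pmax(50L, as.integer(round(stats::rlnorm(
        nG + 1L, config@gapMeanlog, config@gapSdlog))))
      strands <- sample(c("+", "-"), nG, replace = TRUE)
      for (j in seq_along(classes)) {
        p <- .classPlan[[classes[j]]]
        gaps[gapIdx[j] + 1L] <- p$len  # gaps[k+1] follows gene k
        strands[gapIdx[j]] <- p$left
        strands[gapIdx[j] + 1L] <- p$right
      }
      starts <- integer(nG); ends <- integer(nG)
      pos <- gaps[1L]
      for (i in seq_len(nG)) {
        starts[i] <- pos + 1L
        ends[i] <- pos + lens[i]
        pos <- ends[i] + gaps[i + 1L]
      }
      chromSizes[chrom] <- pos
      ids <- sprintf("gene%04d", gidx + seq_len(nG))
      gidx <- gidx + nG
      geneL[[chrom]] <- GRanges(chrom, IRanges(starts, ends),
                                strand = strands, gene_id = ids,
                                description = NA_character_)
      if (length(classes)) {
        gs <- ends[gapIdx] + 1L
        ge <- starts[gapIdx + 1L] - 1L
        summit <- integer(length(classes))
        for (j in seq_along(classes)) {
          summit[j] <- switch(.classPlan[[classes[j]]]$summit,
                              left = gs[j] + 150L,
                              right = ge[j] - 150L,
                              mid = as.integer((gs[j] + ge[j]) %/% 2L))
        }
        interTruthL[[chrom]] <- data.frame(
          chrom = chrom, start = gs, end = ge, class = classes,
          summit = summit,
          left_gene = ids[gapIdx], right_gene = ids[gapIdx + 1L],
          stringsAsFactors = FALSE)
      }
    }
    ## per-chromosome GRanges carry disjoint seqlevels; combining them is
    ## intended here
    genes <- suppressWarnings(do.call(c, unname(geneL)))
    partition <- partitionGenome(genes, chromSizes)

    ## map planted gaps to partition region ids
    interTruth <- if (length(interTruthL))
      do.call(rbind, unname(interTruthL))
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), class = character(0),
                    summit = integer(0), left_gene = character(0),
                    right_gene = character(0))
    ig <- intergenicRegions(partition)
    key <- paste(as.character(seqnames(ig)), start(ig))
    interTruth$region_id <-
      mcols(ig)$region_id[match(paste(interTruth$chrom, interTruth$start),
                                key)]
    roles <- lapply(seq_len(nrow(interTruth)), function(i)
      .plannedRoles(interTruth$class[i], interTruth$left_gene[i],
                    interTruth$right_gene[i]))
    interTruth$promoter_genes <- vapply(roles, function(r)
      paste(r$prom, collapse = ","), character(1))
    interTruth$terminator_genes <- vapply(roles, function(r)
      paste(r$term, collapse = ","), character(1))
    interTruth$region_fe <- stats::runif(nrow(interTruth),
                                         config@intergenicRegionFeRange[1],
                                         config@intergenicRegionFeRange[2])

    ## expression: latent values for every gene; a noDataFraction subset is
    ## withheld from the observable table
    allIds <- mcols(genes)$gene_id
    latent <- stats::rlnorm(length(allIds), log(100), 1.5)
    nNoData <- as.integer(floor(config@noDataFraction * length(allIds)))
    noData <- sample(allIds, nNoData)
    expression <- data.frame(gene_id = setdiff(allIds, noData),
                             value = latent[match(setdiff(allIds, noData),
                                                  allIds)],
                             stringsAsFactors = FALSE)
    tiers <- assignTiers(expression, universe = allIds,
                         qHigh = config@qHigh, qMod = config@qMod)

    ## enriched ORF set: tier-weighted sampling plus forced composites
    tierOf <- stats::setNames(as.character(tiers$tier), tiers$gene_id)
    w <- c(HIGH = 6, MODERATE = 3, LOW_NO = 1, NO_DATA = 2)[tierOf[allIds]]
    w <- (1 - config@rho) * 1 + config@rho * w
    nEnrich <- as.integer(round(config@genicEnrichedFraction *
                                  length(allIds)))
    enriched <- sample(allIds, nEnrich, prob = w)
    promPool <- unlist(lapply(roles[interTruth$class %in%
      c("PROMOTER_SINGLE", "BIDIRECTIONAL_PROMOTER")], `[[`, "prom"),
      use.names = FALSE)
    termPool <- unlist(lapply(roles[interTruth$class %in%
      c("TERMINATOR_SINGLE", "SHARED_TERMINATOR")], `[[`, "term"),
      use.names = FALSE)
    enriched <- union(enriched,
                      utils::head(promPool, config@compositePromoterOrf))
    enriched <- union(enriched,
                      utils::head(termPool, config@compositeOrfTerminator))

    ## fold-enrichment targets tied to latent expression rank
    prank <- (rank(-latent, ties.method = "first") - 0.5) / length(latent)
    score <- config@rho * (1 - prank) +
      (1 - config@rho) * stats::runif(length(latent))
    score <- 0.1 + 0.9 * pmin(1, pmax(0, score))  # guard band above feMin
    fe <- config@feRange[1] + diff(config@feRange) * score^1.8
    ei <- match(enriched, allIds)
    genicTruth <- data.frame(
      gene_id = enriched,
      region_id = enriched,  # genes do not overlap in simulated genomes
      chrom = as.character(seqnames(genes))[ei],
      start = start(genes)[ei], end = end(genes)[ei],
      target_fe = fe[ei], tier = unname(tierOf[enriched]),
      stringsAsFactors = FALSE)
    genicTruth <- genicTruth[order(genicTruth$gene_id), , drop = FALSE]
    rownames(genicTruth) <- NULL

    composites <- list(
      promoter_plus_orf = sort(intersect(enriched, promPool)),
      orf_plus_terminator = sort(intersect(enriched, termPool)))

    list(config = config, genes = genes, chromSizes = chromSizes,
         partition = partition, expression = expression, tiers = tiers,
         genicTruth = genicTruth, intergenicTruth = interTruth,
         composites = composites)
  })
}

#' Simulate IP and input coverage tracks with planted enrichment
#'
#' Input depth is Poisson(\code{lambda}) per base (negative binomial when
#' \code{dispersion} is set). The IP rate profile is flat at baseline with a
#' plateau over each planted gene body and a triangular bump of
#' \code{peakWidth} bp at each planted intergenic summit. Because the
#' enrichment caller normalizes by total track signal, a planted local
#' ratio f is estimated as f divided by the genome-mean profile; the
#' generator therefore solves for the raw profile whose *post-normalization*
#' fold enrichments equal the planted targets, and the returned truth table
#' records the expected normalized region-level fold enrichment of every
#' planted region (computed from the realized profile).
#'
#' @param genome output of [simulateGenome()].
#' @param config the same [SimulationConfig-class].
#' @return list(ip, input) of [CoverageTrack-class] plus \code{truth}
#'   (data.frame region_id, type, class, summit, target_fe, expected_fe) and
#'   \code{profileMean} (the genome-mean IP profile, the normalization
#'   constant).
#' @export
simulateTracks <- function(genome, config) {
  .withSeed(.deriveSeed(config@seed, 2L), {
    cs <- genome$chromSizes
    G <- sum(as.numeric(cs))
    gt <- genome$genicTruth
    it <- genome$intergenicTruth
    halfW <- config@peakWidth / 2

    ## unit shapes: plateaus over planted gene bodies, triangular bumps at
    ## planted intergenic summits (clipped at the region bounds). Every unit
    ## carries a region-level target: the triangle height is solved so the
    ## region average hits it.
    triangle <- function(summit, s, e) {
      xs <- max(s, as.integer(ceiling(summit - halfW)))
      xe <- min(e, as.integer(floor(summit + halfW)))
      x <- seq.int(xs, xe)
      list(start = xs, vals = pmax(0, 1 - abs(x - summit) / halfW))
    }
    shapes <- list(); targets <- numeric(0); lens <- numeric(0)
    for (i in seq_len(nrow(gt))) {
      len <- gt$end[i] - gt$start[i] + 1L
      shapes[[length(shapes) + 1L]] <-
        list(chrom = gt$chrom[i], start = gt$start[i],
             vals = rep(1, len), scalePerExcess = 1)
      targets <- c(targets, gt$target_fe[i]); lens <- c(lens, len)
    }
    for (i in seq_len(nrow(it))) {
      tr <- triangle(it$summit[i], it$start[i], it$end[i])
      len <- it$end[i] - it$start[i] + 1L
      shapes[[length(shapes) + 1L]] <-
        list(chrom = it$chrom[i], start = tr$start, vals = tr$vals,
             scalePerExcess = len / sum(tr$vals))
      targets <- c(targets, it$region_fe[i]); lens <- c(lens, len)
    }

    ## solve the normalization constant C so that planted region-level
    ## targets are the post-normalization fold enrichments: each unit adds
    ## raw mass (t_k * C - 1) * region_length_k
    denom <- G - sum(targets * lens)
    if (denom <= 0)
      stop("planted enrichment mass exceeds genome capacity; ",
           "reduce planted fold enrichments or enlarge the genome")
    C <- (G - sum(lens)) / denom

    profiles <- lapply(cs, function(len) rep(1, len))
    peakFe <- numeric(length(shapes))
    for (k in seq_along(shapes)) {
      s <- shapes[[k]]
      u <- (targets[k] * C - 1) * s$scalePerExcess
      idx <- seq.int(s$start, length.out = length(s$vals))
      profiles[[s$chrom]][idx] <- profiles[[s$chrom]][idx] + u * s$vals
      peakFe[k] <- (1 + u) / C
    }
    draw <- function(mu) {
      if (is.null(config@dispersion)) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), size = config@dispersion, mu = mu)
    }
    ipCov <- lapply(profiles, function(f) Rle(draw(config@lambda * f)))
    inputCov <- lapply(cs, function(len)
      Rle(draw(rep(config@lambda, len))))
    ip <- coverageTrack(methods::as(ipCov, "SimpleRleList"), cs)
    input <- coverageTrack(methods::as(inputCov, "SimpleRleList"), cs)

    ## expected normalized region-level FE from the realized profile
    expFe <- function(chrom, s, e)
      mean(profiles[[chrom]][s:e]) / C
    truth <- rbind(
      if (nrow(gt)) data.frame(
        region_id = gt$region_id, type = "ORF", class = NA_character_,
        summit = as.integer((gt$start + gt$end) %/% 2L),
        target_fe = gt$target_fe,
        expected_fe = mapply(expFe, gt$chrom, gt$start, gt$end),
        stringsAsFactors = FALSE),
      if (nrow(it)) data.frame(
        region_id = it$region_id, type = "INTERGENIC", class = it$class,
        summit = it$summit, target_fe = it$region_fe,
        expected_fe = mapply(expFe, it$chrom, it$start, it$end),
        stringsAsFactors = FALSE))
    if (is.null(truth))
      truth <- data.frame(region_id = character(0), type = character(0),
                          class = character(0), summit = integer(0),
                          target_fe = numeric(0), expected_fe = numeric(0))
    truth$peak_fe <- peakFe
    rownames(truth) <- NULL
    list(ip = ip, input = input, truth = truth, profileMean = C)
  })
}

#' Simulate a ChIP-qPCR measurement table
#'
#' Cq values are drawn from the configured log-linear standard curve with
#' Normal(0, sigma) cycle noise: dilution rows at 100/10/1\% per target, and
#' IP rows at the configured true percent-input per group.
#'
#' @param config a [SimulationConfig-class].
#' @return list(measurements = data.frame as read by [readQpcr()],
#'   truth = data.frame(target, tagged_percent, untagged_percent)).
#' @export
simulateQpcr <- function(config) {
  .withSeed(.deriveSeed(config@seed, 3L), {
    targets <- sprintf("T%d", seq_along(config@taggedPercent))
    cq <- function(pct) config@qpcrIntercept +
      config@qpcrSlope * log10(pct) +
      stats::rnorm(length(pct), 0, config@qpcrSigma)
    rows <- list()
    for (i in seq_along(targets)) {
      dil <- c(100, 10, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        target = targets[i], group = "dilution",
        replicate = seq_along(dil), cq = cq(dil), percent = dil,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        target = targets[i], group = "tagged",
        replicate = seq_len(config@nTagged),
        cq = cq(rep(config@taggedPercent[i], config@nTagged)),
        percent = NA_real_, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        target = targets[i], group = "untagged",
        replicate = seq_len(config@nUntagged),
        cq = cq(rep(config@untaggedPercent[i], config@nUntagged)),
        percent = NA_real_, stringsAsFactors = FALSE)
    }
    list(measurements = do.call(rbind, rows),
         truth = data.frame(target = targets,
                            tagged_percent = config@taggedPercent,
                            untagged_percent = config@untaggedPercent,
                            stringsAsFactors = FALSE))
  })
}

#' Default synthetic peptide-array spot affinities
#'
#' Top spots mirror the acetyl-lysine specificity pattern of a bromodomain
#' reader of active chromatin (led by di-acetylated H3 K9ac+K14ac), plus
#' methyl/phospho background spots with near-zero affinity.
#'
#' @return data.frame(peptide_id, histone, modifications, affinity).
#' @export
defaultPeptideSpots <- function() {
  top <- data.frame(
    peptide_id = sprintf("P%03d", 1:10),
    histone = c("H3", "H2A", "H4", "H4", "H3", "H3", "H4", "H3", "H2A",
                "H2A"),
    modifications = c(
      "K9ac+K14ac", "K5ac+K9ac+K13ac", "R3me2s+K5ac+K8ac+K12ac",
      "K5ac+K8ac+K12ac+K16ac", "K9me3+K14ac", "S10P+K14ac",
      "K5ac+K8ac+K12ac", "T11P+K14ac", "S1P+K5ac+K9ac+K13ac",
      "S1P+K9ac+K13ac"),
    affinity = c(0.95, 0.92, 0.90, 0.89, 0.88, 0.88, 0.84, 0.82, 0.82,
                 0.80),
    stringsAsFactors = FALSE)
  bg <- data.frame(
    peptide_id = sprintf("P%03d", 11:30),
    histone = rep(c("H3", "H4", "H2A", "H2B"), 5),
    modifications = c(
      "K4me1", "K20me1", "K9me1", "K5me1", "K4me2", "K20me2", "K9me2",
      "K5me2", "K4me3", "K20me3", "K9me3", "K5me3", "K27me1", "K8me1",
      "K13me1", "K12me1", "K27me2", "K8me2", "K13me2", "K12me2"),
    affinity = rep(c(0.02, 0.05, 0.01, 0.03, 0.04), 4),
    stringsAsFactors = FALSE)
  rbind(top, bg)
}

#' Simulate a peptide-array intensity table
#'
#' Replicate intensity = affinity + Normal(0, sd), clipped to [0, 1].
#'
#' @param config a [SimulationConfig-class].
#' @param spots optional data.frame(peptide_id, histone, modifications,
#'   affinity); default [defaultPeptideSpots()].
#' @return list(spots = data.frame as read by [readPeptideArray()],
#'   truth = the affinity table).
#' @export
simulateArray <- function(config, spots = defaultPeptideSpots()) {
  .withSeed(.deriveSeed(config@seed, 4L), {
    reps <- vapply(seq_len(config@arrayReplicates), function(r)
      pmin(1, pmax(0, spots$affinity +
                     stats::rnorm(nrow(spots), 0, config@arrayNoiseSd))),
      numeric(nrow(spots)))
    colnames(reps) <- sprintf("rep%d", seq_len(config@arrayReplicates))
    out <- cbind(spots[, c("peptide_id", "histone", "modifications")],
                 as.data.frame(reps))
    list(spots = out, truth = spots)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every format the pipeline reads (GFF3 annotation, chrom.sizes, IP
#' and input bedGraph, expression TSV, qPCR TSV, array TSV) plus truth TSVs.
#' A fixed seed gives byte-identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths plus the in-memory
#'   objects (\code{genome}, \code{tracks}, \code{qpcr}, \code{array}).
#' @export
simulateBundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulateGenome(config)
  tracks <- simulateTracks(genome, config)
  qpcr <- simulateQpcr(config)
  arr <- simulateArray(config)
  p <- function(f) file.path(dir, f)
  writeGenesGff3(genome$genes, p("genes.gff3"))
  writeChromSizes(genome$chromSizes, p("chrom.sizes"))
  writeBedGraph(tracks$ip, p("ip.bedGraph"))
  writeBedGraph(tracks$input, p("input.bedGraph"))
  utils::write.table(genome$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qpcr$measurements, p("qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(arr$spots, p("array.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tracks$truth, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(genome$tiers, p("truth_tiers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(genome$intergenicTruth, p("truth_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  writeLines(c(
    paste0("promoter_plus_orf\t",
           paste(genome$composites$promoter_plus_orf, collapse = ",")),
    paste0("orf_plus_terminator\t",
           paste(genome$composites$orf_plus_terminator, collapse = ","))),
    p("truth_composites.tsv"))
  invisible(list(
    dir = dir, annotation = p("genes.gff3"), chromSizes = p("chrom.sizes"),
    ip = p("ip.bedGraph"), input = p("input.bedGraph"),
    expression = p("expression.tsv"), qpcr = p("qpcr.tsv"),
    array = p("array.tsv"),
    genome = genome, tracks = tracks, qpcr_data = qpcr, array_data = arr))
}
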