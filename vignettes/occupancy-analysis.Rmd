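---
title: "Region-level ChIP-Seq occupancy: models, parameters and design choices"
author: "chipOccupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level ChIP-Seq occupancy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipOccupancy)
```

# The analysis in one paragraph

chipOccupancy quantifies where a chromatin protein sits in a gene-dense
genome. The genome annotation is partitioned into ORF (gene-body) and
intergenic regions that tile each chromosome; every region receives a
library-normalized IP/INPUT fold enrichment from coverage tracks; regions
passing a fold-enrichment threshold together with a localized "strong peak"
are the occupied set. Occupied ORFs are cross-tabulated against
quantile-based expression tiers, and occupied intergenic regions are
classified by which flanking gene ends their peak summit addresses:
promoter (5' of one gene), terminator (3' of one gene), bidirectional
promoter (5' of two divergent genes), shared terminator (3' of two
convergent genes), or a promoter–terminator overlap between tandem genes.
Two bench-side computations round the package out: ChIP-qPCR percent-input
normalization through a log-linear standard curve, and histone
peptide-array intensity ranking.

# The enrichment statistic

For a region $r$ with IP and input depth sums $s^{IP}_r$, $s^{IN}_r$ and
track totals $T^{IP}$, $T^{IN}$,

$$\mathrm{FE}(r) \;=\;
  \frac{(s^{IP}_r + p)\,/\,T^{IP}}{(s^{IN}_r + p)\,/\,T^{IN}},$$

with pseudocount $p$ (default 1 depth-unit per region) guarding division by
zero. Division by the total signal makes the statistic invariant to
sequencing depth: rescaling either track by a constant changes nothing
(pseudocount 0). A consequence worth keeping in mind is that fold
enrichment is always *relative to the genome average*: enriching one part
of the genome necessarily depresses the normalized background elsewhere.
The synthetic-data generator accounts for this explicitly (below).

Regions whose input density falls below a configurable fraction (default
0.1) of the genome-mean input density are flagged `low_input_flag` rather
than dropped, so an unusually empty input never silently manufactures
enrichment.

## Bin labels

Fold-enrichment bins default to half-open intervals $[2,4)$, $[4,6)$,
$[6,8)$, $[8,\infty)$. Published figure legends often count sites
cumulatively ("$\ge t$"), and the two conventions disagree whenever a
region clears more than one threshold, so `binCounts()` and the trend
report expose both; the occupancy–expression monotonicity verdict is
computed on the cumulative layout, which is stable when the top interval
holds few regions.

## Strong peaks

"Occupied" requires more than a high region-level ratio: a localized
sub-region of elevated signal. `strongPeakScan()` slides windows of width
`window` (default 200 bp) at `step` (default 50 bp) across the region
(a region shorter than the window is scanned as one window), computes each
window's fold enrichment, and calls the region strong when the maximal
window reaches the first bin threshold and carries at least
`minWindowIpDepth` (default 5) IP depth. The summit is the center of the
maximal window, ties resolved leftmost so results are deterministic. All
parameters are recorded in report headers because downstream counts depend
on them.

# The genome partition

Internal coordinates are 1-based and closed, the convention of the
GRanges/IRanges containers the package is built on; GFF3 is read natively
and BED's 0-based half-open intervals are converted on import, and every
TSV report prints 1-based inclusive coordinates as a genome browser
displays them. Overlapping or bookended gene models are merged into single
genic spans (member ids retained, reported joined with `|`), because a
disjoint region list is what the per-region statistic needs; the
per-chromosome complement of the genic spans forms the intergenic regions.
How overlapping models should be handled is genuinely open — annotations
rarely say — and merging is the conservative choice that never
double-counts a base. Gaps at scaffold ends keep a single flank and are
flagged `edge`; they participate in enrichment but only single-flank
classes can apply to them.

# Expression tiers

The expression table is any monotone per-gene score (FPKM, counts, a
rank). Genes with data are ranked descending, ties broken by gene id for
determinism; the top $\lceil q_{high} n\rceil$ are HIGH and the next
$\lceil q_{mod} n\rceil$ MODERATE, defaults 9% and 29% — the global
fractions reported for vegetatively growing *Tetrahymena* — with the rest
LOW_NO. Genes absent from the table form the first-class NO_DATA tier
rather than being dropped, since in the motivating data set a noticeable
share (~14%) of occupied ORFs had no expression measurements and silently
discarding them would bias the cross-tabulation. The numeric cutoffs
behind "highly expressed" are nowhere published as absolute values, which
is why tiers are quantile-based and both fractions are arguments.

# Intergenic classification

The motivating study classified enriched intergenic regions by eye in a
genome browser. The package codifies that judgement with one distance
parameter: a flanking gene is *addressed* when the peak summit lies within
`dMax` (default 300 bp) of the gene end abutting the region. Strand
decides which end abuts: a left-flank gene on `+` meets the region with
its 3' end, on `-` with its 5' end, mirrored on the right. Regions no
longer than `bothFlankLen` (default `2 * dMax`) address both present
flanks regardless of summit position — in a 400 bp gap there is no
meaningful "far" flank. The class then follows from the addressed ends:
two 5' ends give BIDIRECTIONAL_PROMOTER, two 3' ends SHARED_TERMINATOR,
one of each PROMOTER_TERMINATOR_OVERLAP, a single 5' or 3' end the single
promoter/terminator classes, and none UNCLASSIFIED. UNCLASSIFIED is
deliberately allowed: forcing every region into a named class would hide
what the distance convention actually does. When a region has no
strong-peak summit the midpoint substitutes, flagged
`midpoint_fallback`. `dMax` is a free parameter — the visual criterion the
original analysts applied is unknowable — so it is printed in every class
report header.

Combined categories connect the two region types: an occupied ORF whose
own promoter-side region is classified PROMOTER_SINGLE or
BIDIRECTIONAL_PROMOTER (addressing that ORF) is promoter+ORF;
TERMINATOR_SINGLE or SHARED_TERMINATOR on the 3' side gives
ORF+terminator. An ORF can hold both. Overlap-class regions qualify for
neither, since there the promoter role already belongs to a different
gene's reading of the region.

# Over-representation analysis

Functional grouping of occupied genes is a plain hypergeometric
upper-tail test per term with Benjamini–Hochberg control across terms —
the original network-tool grouping has no published statistic to
reproduce, and the claim being checked is over-representation, nothing
more. Genes without any annotation stay in the universe by default
(conservative; shrinking the universe to annotated genes inflates
significance), with `dropUnannotated` to switch.

# qPCR and peptide array

The standard curve is the least-squares fit $C_q = a + b\log_{10}(\%)$ on
a dilution series (the emulated design: 100/10/1% of input), inverted as
$\% = 10^{(C_q - a)/b}$; amplification efficiency is $10^{-1/b}-1$, 100%
at $b = -1/\log_{10}2 \approx -3.32$ cycles per ten-fold dilution, and
curves with $b \ge 0$ are flagged invalid. Group comparison uses Welch's
two-sided t-test by default because the emulated design has unequal group
sizes (4 tagged vs 3 untagged chromatin preparations) and nothing
guarantees equal variances; Student's pooled test is available via
`varEqual`. When both groups are constant and equal, $t = 0,\ p = 1$ by
convention. SEM is $sd/\sqrt{n}$ across biological replicates per group.

Peptide-array spots are averaged across replicates and ranked descending,
ties by peptide id. Tables outside $[0,1]$ are min–max normalized across
the whole array first (the published 0–1 scale is otherwise unspecified);
tables already in $[0,1]$ pass through, overridable. When histone
sequences are supplied, each modified residue is checked against the
sequence and mismatches — residues absent from the target species'
histone — are listed per spot. The shipped
`synthetic_histones.fasta` is a constructed stand-in: canonical H3/H2A/H2B
N-terminal tails plus an H4 tail whose arginine 3 is replaced by glycine,
modelling the documented case of a modified residue missing from the
organism's histone.

# The synthetic-data generator

`simulateGenome()`/`simulateTracks()` produce a complete, fully-known
study: a two-chromosome annotation of 200 genes (log-normal lengths,
median 1.5 kb; log-normal intergenic gaps, median 400 bp — a gene-dense
genome), all four flank orientations, a planted count of every intergenic
class, per-gene expression with 9%/29% tiers and 14% withheld as NO_DATA,
and coverage with per-base Poisson noise at base depth $\lambda = 30$
(negative-binomial via `dispersion` for overdispersion). Occupancy is
planted preferentially in highly expressed genes: selection weights and
the fold-enrichment mapping both follow the expression rank with strength
$\rho$ (default 0.8), so the occupancy–expression trend the pipeline
should detect is real by construction, spanning planted fold enrichments
of 2–13.

Three generator choices deserve explanation:

* **Normalization closure.** Because fold enrichment is measured relative
  to the genome mean, a raw local ratio $f$ is *estimated* as $f/C$, where
  $C$ is the genome-mean IP profile. The generator therefore solves for
  the raw profile whose post-normalization enrichments equal the planted
  targets ($C$ has a closed form given the planted targets and their
  footprints), and validates that the planted mass fits below genome
  capacity. Truth tables record the expected normalized region-level
  value computed from the realized profile, so recovery comparisons are
  noise-limited, never bias-limited.
* **Region-level intergenic targets.** Planted intergenic units are
  parameterized by the region-level fold enrichment (default range
  [3, 6]); the 400 bp triangular summit peak is solved to make the region
  average hit the target. Parameterizing the peak height instead would
  leave long promoter/terminator gaps below the ≥2 filter after
  normalization.
* **Guard band.** Planted genic enrichments start slightly above the
  lowest threshold (the rank-to-FE map is floored), so exact
  planted-count recovery is a property of the method, not a coin flip on
  regions sitting exactly at 2.0.

Geometry of planted classes assumes the default classifier (`dMax`
300 bp): single-flank classes use 1200 bp gaps with the summit 150 bp from
the addressed end, both-flank classes use 400 bp gaps. The default planted
load (5% of genes plus a few forced promoter+ORF / ORF+terminator
composites, ~7.5% of genes total) keeps the planted signal mass well below
genome capacity for every seed.

What the generator does *not* model: fragment-size effects, GC or
mappability bias, duplicate reads, replicate structure. Passing tests
therefore demonstrate that the statistics and classifiers recover what
they define on clean count noise — not that any particular biological
data set is free of the artifacts real ChIP-Seq carries. Problem sizes
used by the shipped tests are deliberate: toy per-base oracles run on
≤10 kb chromosomes; parameter recovery runs once at 200 genes on a ~2 Mb
genome (gap median widened to 8 kb so that >100 planted regions fit below
genome capacity), where the per-region ratio error at $\lambda = 30$ is
about 1–2%, an order of magnitude inside the ±10% recovery band.

# Determinism

Every simulator takes its stream from one master seed (fixed generator
kinds), and each sub-generator derives an independent seed, so a bundle
is byte-identical across runs and machines; the pipeline itself is purely
deterministic, and its manifest records every tunable plus input
checksums. Ties anywhere (ranking, tiers, summits) break by identifier or
leftmost position, never by hash order.

# Known limitations

* The strong-peak scan is a fixed-width heuristic, not a peak caller with
  a background model; regions with multiple separate peaks report only
  the maximal window.
* Fold enrichment at very low input coverage is flagged, not corrected;
  there is no duplicate handling or replicate-aware (IDR-style)
  reconciliation.
* The classifier is purely positional. "Promoter" means 5'-proximal
  intergenic space; no TSS, motif or nucleosome evidence is consulted.
* Quantile tiers inherit whatever biases the upstream expression score
  carries; the package deliberately does not quantify expression itself.
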