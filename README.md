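# chipOccupancy

Region-level analysis of ChIP-Seq occupancy in gene-dense genomes, built
for the question a chromatin-reader study asks: *which genes and which
regulatory spaces does this protein occupy, and how does occupancy relate
to transcription?* The package is aimed at analysts working with compact
genomes (ciliates, yeasts, other microbial eukaryotes) where genes sit a
few hundred base pairs apart and "peak annotation" means deciding which
gene end an intergenic peak addresses.

## What it computes

* **Genome partition** — genes (GFF3/BED) are merged into disjoint ORF
  spans whose per-chromosome complement forms the intergenic regions;
  every intergenic region carries its nearest flanking gene and strand on
  each side, and genic + intergenic spans tile each chromosome exactly.
* **Fold enrichment** — per region, library-normalized IP/INPUT:

  FE(r) = ((ip_r + p)/T_ip) / ((input_r + p)/T_input)

  with pseudocount `p`, plus a sliding-window *strong peak* call
  (window-level FE ≥ first threshold with a minimum IP depth) that
  supplies a summit. Regions are ranked descending and binned at
  thresholds 2/4/6/8.
* **Occupancy × expression** — quantile tiers (defaults: top 9% HIGH,
  next 29% MODERATE, remainder LOW_NO, absent genes NO_DATA) are
  cross-tabulated against the occupied ORF set, with a per-bin trend
  report asking whether the HIGH fraction rises with fold enrichment.
* **Intergenic classification** — each enriched intergenic region is
  classified from its summit and flanking-gene orientations into
  PROMOTER_SINGLE, TERMINATOR_SINGLE, BIDIRECTIONAL_PROMOTER,
  SHARED_TERMINATOR, PROMOTER_TERMINATOR_OVERLAP or UNCLASSIFIED, and
  combined promoter+ORF / ORF+terminator categories are derived.
* **Over-representation** — hypergeometric upper-tail test per term with
  Benjamini–Hochberg FDR.
* **Assays** — ChIP-qPCR percent-input via a log-linear standard curve
  (Cq = a + b·log10(%), efficiency 10^(−1/b) − 1, Welch t-test between
  tagged and untagged groups) and histone peptide-array ranking with
  residue-conservation flags.
* **Synthetic data** — a seeded generator emits every input format the
  pipeline reads (GFF3, chrom.sizes, bedGraph, TSVs) plus truth tables,
  so the whole pipeline is testable end to end without downloads.

## Worked example

Simulate a study-scale data set and run the pipeline on the written files:

```r
library(chipOccupancy)

cfg <- simulationConfig(seed = 42)
bundle <- simulateBundle(cfg, "demo_bundle")
res <- runOccupancy(
  annotation = bundle$annotation, chromSizes = bundle$chromSizes,
  ip = bundle$ip, input = bundle$input, outDir = "demo_out",
  expression = bundle$expression, qpcr = bundle$qpcr, array = bundle$array)

res$partition
#> GenomePartition: 2 chromosome(s), 200 gene(s)
#>   genic spans:     200
#>   intergenic:      202 (4 edge)
#>   genome length:   413960 bp

occ <- filterEnriched(res$enrichment, 2, strongOnly = TRUE)
nrow(occ)
#> [1] 38
head(occ[, c("region_id", "type", "fold_enrichment", "bin", "summit")], 3)
#>   region_id type fold_enrichment bin summit
#> 1  gene0006  ORF        12.46459 >=8  12153
#> 2  gene0007  ORF        12.02046 >=8  13909
#> 3  gene0040  ORF        10.72612 >=8  83908
```

38 regions pass FE ≥ 2 with a strong peak — exactly the 38 the generator
planted (15 ORFs, 23 intergenic). The occupied set skews toward expressed
genes relative to the genome background:

```r
res$crosstab
#>       tier count_enriched pct_enriched count_universe pct_universe
#> 1     HIGH              2     13.33333             16            8
#> 2 MODERATE              4     26.66667             50           25
#> 3   LOW_NO              9     60.00000            106           53
#> 4  NO_DATA              0      0.00000             28           14

## the pipeline report classifies the >= 4x set; classifying the full
## >= 2x enriched set recovers the planted composition exactly
cl <- classifyAll(filterEnriched(res$enrichment, 2, type = "INTERGENIC"),
                  res$partition)
cl$counts
#>             PROMOTER_SINGLE           TERMINATOR_SINGLE
#>                          10                           5
#> PROMOTER_TERMINATOR_OVERLAP      BIDIRECTIONAL_PROMOTER
#>                           2                           3
#>           SHARED_TERMINATOR                UNCLASSIFIED
#>                           3                           0
```

All 23 planted intergenic classes (10/5/2/3/3) are recovered from the
estimated summits. The qPCR module fits each target's dilution curve and
compares tagged against untagged chromatin:

```r
res$qpcr[, c("target", "slope", "efficiency", "fold_change", "p")]
#>   target slope efficiency fold_change        p
#> 1     T1 -3.24      1.035        8.59 2.38e-04
#> 2     T2 -3.38      0.975        5.55 3.64e-04
#> 3     T3 -3.30      1.010        4.64 5.93e-05
#> 4     T4 -3.34      0.992        0.97 5.35e-01
```

Targets T1–T3 (planted enrichment) are significant; the unenriched control
T4 is not. The closed-form curve behaves as qPCR arithmetic demands:

```r
curve <- fitStandardCurve(c(100, 10, 1), c(20.00, 23.32, 26.64))
curve
#> StandardCurve: Cq = 26.6400 -3.3200 * log10(%input); R2 = 1.0000; efficiency = 100.1%
percentInput(23.32, curve)
#> [1] 10
```

Every report lands in `demo_out/` as TSV (partition, ranked enrichment
tables at each threshold, tier crosstab and trend, intergenic classes,
combined categories, qPCR, array ranking) alongside a `manifest.tsv`
recording every parameter and input checksum.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/occupancy-pipeline.R", package="chipOccupancy"))')" \
  --simulate --seed 42 --out demo_out
```

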