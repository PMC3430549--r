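# syntenyviz

Visualization-ready analysis of multi-genome synteny from user-supplied
coordinate data.

Comparative genomics pipelines (MCScan-style synteny detection, whole
genome aligners, plain BLAST) end in tables of *conserved region pairs*:
an interval on one genome matched to an interval on another, with scores
attached.  `syntenyviz` is an R toolkit for the step after that — turning
those tables into filtered, well-ordered, publication-ready synteny
figures — aimed at biologists comparing their own handful of genomes,
strains or loci rather than a curated reference set.  It is
coordinate-only by design: sequences are never read.

The package provides:

* **An open-ended interchange format.**  Tab-delimited synteny files with
  six mandatory columns (`org1 org1_start org1_end org2 org2_start
  org2_end`, 1-based inclusive bp) and any number of extra attribute
  columns, plus an eight-column annotation format with per-feature shape,
  color and hyperlink.  Plain, gzip or single-member zip input.
* **Converters** from BLAST tabular (`-outfmt 6`), axt alignments, and
  GFF3.
* **Numeric filtering** of conserved regions on any attribute or on the
  derived region `length`.
* **Genome track ordering.**  The weight between two genomes is their
  total conserved size
  `w(i,j) = Σ ((end1−start1+1) + (end2−start2+1))/2` over shared blocks.
  Pairwise viewing mode maximizes the adjacent-pair sum
  `Σ_k w(π_k, π_{k+1})` (greedy max-weight path); multiple viewing mode
  minimizes the size-weighted track crossings
  `Σ_{i<j} w(i,j)·max(0, |pos(i)−pos(j)|−1)` (greedy insertion plus
  swap/reversal local search).  An exhaustive oracle (≤ 8 genomes) gives
  the exact optimum for comparison.
* **Deterministic SVG rendering**: pairwise stacks (repeated genomes
  allowed, annotation tracks shown), multiple-mode stacks (all pairs, one
  color per pair, per-pair hiding), and a circular overview with arcs
  proportional to genome extent, chords per association, and the
  association table.
* **A seeded synthetic-data generator** with a planted genome chain,
  used as ground truth by the tests.
* **A command line** (`exec/syntenyviz`): `validate`, `summary`, `order`,
  `render`, `convert`, `simulate`.

## Worked example

```r
library(syntenyviz)

blocks <- read_synteny(textConnection(paste(
  "org1\torg1_start\torg1_end\torg2\torg2_start\torg2_end\tpident",
  "chr1\t1000\t8000\tchrA\t2000\t9500\t92.1",
  "chr1\t20000\t26000\tchrB\t500\t6600\t88.0",
  "chrA\t15000\t18000\tchrB\t11000\t13900\t75.5",
  "chr1\t40000\t41000\tchrB\t30000\t31050\t61.0",
  sep = "\n")))
d <- synteny_dataset(blocks)
d
#> synteny_dataset: 4 blocks, 0 features, 3 genomes
#> genomes: chr1, chrA, chrB

association_summary(d)
#>   genome1 genome2 n_regions total_size
#> 1    chr1    chrB         2       7077
#> 2    chr1    chrA         1       7251
#> 3    chrA    chrB         1       2951

optimize_pairwise_order(build_weight_graph(d))
#> chrB - chr1 - chrA
#> mode: pairwise  score: 14328
```

The association table lists each genome pair sharing conserved regions
with the region count and total conserved size in bp (each block
contributes the mean of its two side spans — here chr1–chrA share one
block of mean span 7251 bp).  The suggested track order puts chr1, the
genome with heavy links to both others, in the middle: stacking
chrB–chr1–chrA makes 14328 bp of conserved sequence visible between
adjacent tracks, the maximum possible for these weights.

Filtering and rendering:

```r
apply_filters(blocks, filter_criterion("pident", min = 80))  # 2 blocks
svg <- render_pairwise(d, c("chrB", "chr1", "chrA"))
writeLines(svg, "synteny.svg")
```

Equivalently from a shell:

```sh
syntenyviz summary synteny.tsv
syntenyviz order synteny.tsv --mode pairwise
syntenyviz render synteny.tsv --mode pairwise --optimize \
    --filter pident:80: --out synteny.svg
```

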