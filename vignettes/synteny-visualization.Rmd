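---
title: "Methods: multi-genome synteny visualization and track ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-genome synteny visualization and track ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenyviz)
```

## The problem

Synteny — conservation of genomic features and of their relative order
between genomes — is usually established upstream by an alignment or
synteny-detection tool, and then has to be *seen* to be understood:
patterns of conservation and rearrangement across several genomes are too
complicated to read off coordinate tables.  `syntenyviz` is a
coordinate-only toolkit for this last step.  It never reads sequence; its
unit of data is the *conserved region pair* (synteny block): an interval
on genome A asserted to correspond to an interval on genome B, plus any
number of user-supplied numeric or text attributes (alignment score,
percent identity, ...).

The package covers the full path from third-party output to figure:

1. an open-ended tab-delimited interchange format (readers, writers,
   gzip/zip decompression);
2. converters from BLAST tabular, axt and GFF3;
3. numeric filtering of blocks on their attributes;
4. optimization of the vertical order of genome tracks, for two distinct
   viewing modes;
5. deterministic SVG rendering (pairwise stack, all-pairs stack, circular
   overview);
6. a seeded synthetic-data generator used throughout the tests.

## The interchange format

A synteny file is tab-delimited with a mandatory header whose first six
columns are `org1 org1_start org1_end org2 org2_start org2_end`.
Coordinates are 1-based inclusive base pairs, normalized so start ≤ end
on each side; a block's orientation, when known, travels in an attribute
column such as `strand`.  Any further header columns are *attributes*:
the format is open-ended precisely so that whatever characteristics the
upstream tool emits become filterable without schema changes.  A column
is typed numeric iff every non-blank cell parses as a finite number;
`NA` and the empty string count as text.  This per-column rule is what
makes filtering semantics predictable: a column polluted by a single
textual value is text, and blocks in it are dropped under any numeric
filter on that column.

The annotation format has exactly eight columns
(`org start end strand feature track shape color`); the `feature` cell
may be `name|URL`, which splits into a display name and a hyperlink.
Shapes come from the closed vocabulary {box, arrow, line} and strand from
{+, −, .}.

Writers render numeric values with `format(digits = 15, scientific =
FALSE)`: plain decimal notation that re-reads to the same double, so
write → read → write is byte-stable and read → write → read is
structure-identical.  Files may be plain, gzip, or single-member zip;
gzip is also recognized by magic bytes when the extension lies.

### Derived quantities

The per-block *size* is the mean of the two side spans,
$\;((e_1 - s_1 + 1) + (e_2 - s_2 + 1)) / 2$.  The two sides of a block
may legitimately differ in length (indels), and the mean is the symmetric,
scale-correct summary.  The same number is the derived `length` filter
attribute, the contribution of a block to the association summary's
`total_size`, and the edge weight of the ordering graph — one definition,
used everywhere.

## Filtering

A `filter_criterion(attribute, min, max)` is a conjunctive numeric range;
unset bounds are infinite.  A block passes iff **every** criterion finds
a numeric value inside its range.  Blocks *lacking* the attribute, or
carrying text there, are dropped when that attribute is filtered: the
motivating use case is a stringency cutoff ("show only highly conserved
regions"), and an unknown value must not sneak past a cutoff.  The
consequences — monotonicity under bound tightening, idempotence,
order-independence — are tested as properties against a brute-force
per-block scan.

In the pairwise view each adjacent-pair track filters independently, and
the filter is keyed by *track position*, not by genome-pair identity: with
a repeated genome (order `B-A-C-A-D`) the two `A`-adjacent tracks may be
filtered differently.  The multiple view has a single global filter.

## Genome track ordering

Let $w(i,j) \ge 0$ be the total conserved size between genomes $i$ and
$j$ (sum of block sizes; `build_weight_graph()`).  An alternative weight,
the association *count*, is available via `weight = "count"`.

**Pairwise objective.** Blocks are only drawn between adjacent tracks, so
a good order maximizes
$\sum_k w(\pi_k, \pi_{k+1})$ — a maximum-weight Hamiltonian path.
The greedy construction seeds with the heaviest edge and repeatedly
appends, at either path end, the unused genome with the largest weight to
that end (ties: lexicographically smaller name; equal-weight end ties:
the right end; zero-weight leftovers: appended right, name-sorted).

**Multiple objective.** All pairs are drawn, and a link between tracks
$p$ and $q$ crosses $|p-q|-1$ intermediate tracks.  The cost is
$\sum_{i<j} w(i,j)\,\max(0, |\mathrm{pos}(i)-\mathrm{pos}(j)|-1)$, a
size-weighted crossing count (a weighted linear-arrangement objective).
The heuristic inserts genomes in decreasing total weight — starting from
the heaviest pair — each at the position minimizing the partial cost
(ties leftmost), then runs a steepest-descent local search.

The local search tries **adjacent swaps and segment reversals** until no
move improves.  Reversals are essential, not cosmetic: greedy insertion
can lay down a chain segment in reverse orientation relative to the rest
of the order, a state from which no sequence of individually-improving
adjacent swaps can escape.  A concrete stuck case is the path-weight
graph A–F with consecutive weights (10, 9, 2, 8, 20): insertion ends at
`C B A D E F`-type orders costing $2\,w(C,D)$, every adjacent swap is
non-improving, yet reversing the first segment reaches the zero-cost
chain.  With reversals included, the heuristic recovers planted chains in
100/100 seeded instances (tested), while remaining a heuristic: on
unstructured random graphs it attains the exhaustive optimum in roughly
80–90% of 6-genome instances (the acceptance script reports the measured
fractions) and never beats it.

`exhaustive_order()` enumerates all permutations — refused above 8
genomes (40320 orders) since factorial growth makes larger instances
unreasonable for an oracle — with deterministic lexicographic
tie-breaking.  Both heuristics emit simple permutations; repeated-genome
layouts in the pairwise view remain a manual choice passed directly to
the renderer, since repetition is a presentation decision (which
comparisons to show twice), not an optimization target.

All tie-breaks throughout (seed-pair choice, candidate genome, insertion
position, permutation enumeration) are lexicographic and therefore
reproducible.

## Rendering

Rendering is a pure function from (dataset, order, viewports, filters,
style) to an SVG 1.1 string: no timestamps, no RNG, fixed formatting of
numbers (two decimals, trailing zeros trimmed), so identical inputs give
byte-identical bytes — which the tests verify with direct string
comparison.

* Each genome occurrence is a horizontal ruler with tick marks.  The tick
  interval is the largest $\{1,2,5\}\times10^k$ value yielding 4–10
  ticks; labels carry bp/kb/Mb units.  Coordinates map affinely from the
  visible interval `[from, to]` onto `[0, width]`, with out-of-view
  positions clamped to the edges and flagged; blocks invisible on *both*
  sides are omitted, partially visible ones are clipped.  Consequently
  every emitted polygon x-coordinate lies within the drawing area — a
  tested invariant.
* Pairwise mode: translucent quadrilaterals between adjacent rulers;
  per-block colors cycle a fixed 12-color qualitative palette in drawing
  order (or a uniform color); one selected annotation track is drawn
  inside each ruler (box / strand-pointing arrow / line), hyperlinked
  features wrapped in `<a>` elements; tooltips (`<title>`) carry the
  numerical start and end positions.
* Multiple mode: blocks for *all* genome pairs in view, each pair in one
  shared color so overlapping ribbons remain attributable; non-adjacent
  links pass over intermediate rulers as translucent ribbons; individual
  pairs can be hidden; no annotations (each genome appears at most once).
* Overview: genomes as circle arcs with angular span proportional to
  extent (arc spans sum to 360° minus the inter-arc gaps), one chord per
  associated pair with stroke width proportional to total conserved size,
  and the association table (pair, count, total bp) beside the circle.

The genome *extent* used for full-genome rulers and the overview is
`[1, max observed coordinate]`, overridden by a declared genome length
when that is larger (a declared length below an observed coordinate is a
warning-level diagnostic, not an error).  Observed-maximum fallback keeps
files that declare nothing fully usable.

Block geometry is a straight-edged quadrilateral; curved ribbons would be
purely cosmetic.  Static SVG with viewport parameters replaces
interactive zoom/pan; tooltips and hyperlinks preserve the click-to-
inspect affordances in static form.

## Synthetic data

`generate_dataset(fixture_spec(...))` draws a hidden random permutation
of the genomes (the "true chain") and places a fraction
`chain_strength` of the blocks between consecutive chain genomes, the
rest between uniformly random pairs.  Block spans are lognormal with
median 5 kb and `sdlog = 1` — covering sub-kilobase fragments through
multi-ten-kilobase regions, the range typical of microbial synteny maps —
with uniform starts in a 1 Mb genome; default extra columns are a uniform
`pident` in [50, 100] and a lognormal `score`.  Defaults (5 genomes, 40
blocks) are desk-scale; order-recovery experiments in the tests use 6
genomes × 60 blocks so that the exhaustive oracle (720 permutations)
stays instant while weights are well-populated.  Generation is
deterministic per seed and leaves the caller's RNG stream untouched.

The generator emulates coordinate structure and attribute distributions
only.  It does not emulate inversions and translocations with realistic
breakpoints, unequal genome sizes, coordinate overlap structure between
blocks, or correlated attributes.  Passing tests therefore demonstrate
correctness of the *mechanics* (parsing, filtering, ordering objectives,
geometry) on data of realistic shape — not biological validity of any
particular synteny map.

## Limitations

* Attribute typing is per column, not per cell; one stray textual value
  makes a column text (and its blocks fall to any numeric filter on it).
* The ordering heuristics are greedy with local search; optimality is
  guaranteed only against the ≤ 8-genome exhaustive oracle in tests.
* Self-synteny blocks are accepted and counted in association summaries,
  but carry no weight in ordering and are not drawn between distinct
  tracks.
* Header spellings other than the fixed dialect tokens are rejected
  rather than guessed.
* Rendering targets static SVG 1.1; there is no interactive output, PNG
  rasterization, or dot-plot view.
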