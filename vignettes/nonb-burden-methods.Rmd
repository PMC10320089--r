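---
title: "Methods: non-B DNA burden computation and motif screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-B DNA burden computation and motif screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbburden)
```

## The burden model

Non-B DNA structures form at characteristic sequence motifs, and databases
of predicted motifs (genome-wide, per structural type) are the standard
starting point for analysing them. `nbburden` treats such a library as a
fixed universe of intervals and defines, for a query region set and one
structural type, the **non-B burden** as the number of *distinct* motifs of
that type overlapping the query, under one of four normalizations:

| mode | value | comparable across |
|------|-------|-------------------|
| `raw` | $C$ | nothing (integer count) |
| `per_kb` | $C \cdot 10^3 / L$ | regions of different length |
| `per_million` | $C \cdot 10^6 / N$ | types of different abundance |
| `cpkm` | $C \cdot 10^3 \cdot 10^6 / (N \cdot L)$ | both (default) |

where $C$ is the overlap count, $L$ the merged query length in bp, and $N$
the genome-wide library size of the type. CPKM (counts per kilobase per
million) is the default unit because gene lengths span two orders of
magnitude and type library sizes span three (a few thousand A-phased
repeats versus millions of inverted repeats in genome-scale libraries), so
neither raw counts nor single normalizations compare meaningfully across
both axes at once.

Assumptions baked into the model:

* **Any overlap counts.** A motif contributes if it shares at least 1 bp
  with the query union — the convention of `bedtools intersect` and
  `GenomicRanges::countOverlaps`, which perform the interval arithmetic
  here. Requiring full containment is available via `contained_only =
  TRUE` for users who want conservative counts; it systematically excludes
  motifs straddling query boundaries.
* **Deduplication within a unit, independence across units.** A motif
  overlapping two regions of the same query unit counts once ($C$ counts
  motifs, not intersections); the same motif may count in several units of
  a batch, because each unit is an independent query. Consequently,
  per-unit counts over a partition of a region can exceed the count over
  the union — exactly when motifs span partition boundaries.
* **Merged length.** $L$ sums interval lengths after per-chromosome
  merging of overlapping and book-ended regions, so duplicated or
  overlapping input regions do not deflate the burden. An empty query has
  no defined denominator and is an error, as is a type with $N = 0$ under
  library-size normalization — returning 0 silently would be
  indistinguishable from a genuinely motif-free region.
* **Strand is ignored.** Non-B motif formation is a property of the duplex
  locus; strand is carried through IO but never conditions counting.
* **Coordinates.** Everything internal is 0-based half-open (BED
  convention). The 1-based inclusive TSV dialect is converted at the file
  boundary, so all overlap math lives in one convention; touching
  half-open intervals (`[a,b)` vs `[b,c)`) do not overlap.

**Gene model.** Motif databases do not come with a gene model, and
different annotations disagree on transcript extents. A queried gene is
defined here as the merged union of *all* annotated intervals carrying its
symbol (across transcripts, and across chromosomes with a warning). This
is the least arbitrary rule available without fixing a specific
annotation release, but it means absolute gene-level burdens depend on the
annotation supplied: values computed against different gene models are
not directly comparable.

**Type vocabulary.** Seven parent types (APR, G4, Z, IR, MR, DR, STR) plus
two flagged subsets, Triplex-MR ⊂ MR and Cruciform-IR ⊂ IR. Subsets are
flags on parent records, not separate records: parent library sizes
include them, and subset burdens count flagged records only. Matrices
default to the 7 parent types with subsets opt-in
(`include_subsets = TRUE`); batch outputs are written types × groups on
disk, the natural orientation when groups (samples) are the observational
unit.

## Gene screen

The descriptive layer works on any single-mode burden table or matrix:

* `total_burden()` — row sums, the stacked-bar quantity.
* `composition()` — per-type fractions of a unit's total; undefined (an
  error, not 0/0 noise) for all-zero units.
* `burden_intervals()` — "high/low from the burden distribution" needs a
  concrete rule; two are provided and named in the output: `sd` (mean ±
  k·SD, default k = 1) and `quantile` (default 25th/75th percentiles).
  The SD rule is the default because it is the conventional reading of
  "statistical interval", but it is sensitive to outliers; the quantile
  rule is the robust alternative. A constant column yields all-`mid` with
  a warning rather than arbitrary splits.
* `cluster_burden()` — agglomerative hierarchical clustering
  (`stats::hclust`) of both axes; Euclidean distance and complete linkage
  by default, the standard heatmap choice, with both parameters exposed.
  Leaf orders are deterministic (hclust's tie-breaking by input order),
  and complete-linkage merge heights are monotone non-decreasing, which
  the tests assert.

## Motif screen

Motif quality for non-B formation is screened on sequence features:
length (nt), %G and %A (percent, 0–100, case-insensitive; `N` bases count
in the denominator only, and all-`N` motifs are excluded from clustering
with a warning). Features come from stored sequences or are fetched from
a reference FASTA.

Clustering is k-means (`stats::kmeans`, Lloyd updates) with **k-means++
seeding** implemented from a user seed, so identical inputs and seed give
bit-identical assignments; the RNG state of the session is restored
afterwards. Features are **z-scored by default**: length is in
nucleotides (tens) and compositions in percent (tens), but their variances
differ and unscaled Euclidean distance would weight them arbitrarily;
`standardize = FALSE` disables this for users who want raw-unit geometry.
A constant feature cannot be z-scored and is dropped with a warning.
Reported centroids are back-transformed to original units.

`k` defaults to 4 — small enough to be interpretable on a 2-D feature
plot, large enough to isolate a high-%G/long-length candidate cluster —
but no automatic selection is attempted; `kmeans_elbow()` reports total
within-cluster SS across candidate k for manual inspection. If Lloyd
iteration lands on an empty cluster (possible with duplicated points),
the fit is retried on a deterministically perturbed copy (±1e-9, seeded),
keeping reruns identical. At `k = n` the saturated solution (each point
its own cluster, WSS exactly 0) is returned directly.

`select_motifs()` is deliberately thin — arbitrary `dplyr::filter()`
predicates over the computed features and cluster labels, preserving
input order, with an empty result being an empty table rather than an
error.

## Flank extraction

`extract_flanked()` slices `flank_len` nt of context either side of a
motif from the reference, clipping at `[0, contig length)` and flagging
clipped records. The invariant — concatenated left flank + motif + right
flank equals the direct genome substring of the padded interval — is what
the tests check on random cases. Minus-strand motifs are *not*
reverse-complemented by default (plus-strand display is the convention
for flanked output); `orient_by_strand = TRUE` reverse-complements and
swaps the flanks. FASTA output soft-masks flanks (lowercase) so the
flank/motif boundary survives round-trips without a separator character;
the display format joins parts with an em dash.

## Synthetic fixtures: what they do and do not show

`make_toy_genome()` emits uniform-random A/C/G/T contigs;
`plant_motifs()` places non-overlapping motif records into them, writing
each motif's sequence into the genome with an exact number of G's
(target %G to within one base), and returns a truth table.
`expected_counts()` computes expected overlap counts from that table by
brute-force pairwise interval arithmetic — deliberately independent of
the GenomicRanges-based engine, so engine and oracle cross-check each
other. Planted motifs never overlap one another by default, keeping
truth-table counts unambiguous; `allow_overlap = TRUE` exists for stress
tests where that guarantee is given up.

The `case3-mini` preset emulates the shape of a burden-in-batch study at
desk scale: 104 sample groups of 10 mutation-site regions over a
2 × 60 kb genome with all 7 types planted (516 motifs; MR and IR carry
30% subset flags) — 104 groups being the canonical batch size of a
per-patient mutation-site cohort, and the remaining sizes chosen so the
full preset generates in seconds. Type counts preserve the qualitative
abundance ranking of genome-scale libraries (IR most abundant, APR
rarest) at a scale ~10^4 smaller.

What passing these tests shows: the counting, normalization, batching,
clustering and slicing machinery is exact on inputs with known truth.
What it does not show: anything about real non-B biology. Uniform-random
genomes have no repeat structure, planted motifs have no quadruplex/
Z/cruciform grammar, and toy library sizes make CPKM magnitudes
incomparable to genome-scale values. Reproducing published gene-level
CPKM values additionally requires the specific motif database release
*and* the (undocumented) gene model behind them; with a user-supplied
library and annotation the package computes them, but no such content is
bundled.

## Numerical choices

* All count arithmetic is promoted to double before the
  $10^3 \cdot 10^6$ scaling — $N \cdot L$ overflows 32-bit integers for
  genome-scale inputs.
* Burden values carry full double precision; 2-decimal display is
  formatting, never storage.
* Matrix TSVs print numbers at 15 significant digits, so write/read
  round-trips are exact in practice.
* Composition fractions reconstruct values to 1e-9 (tested); banding ties
  (values exactly at a threshold) are `mid`, making `high` and `low`
  strict exceedances.
* Every generator and clustering call restores the session RNG state, so
  seeded calls do not perturb surrounding analyses.

## Problem sizes used in the test suite

Random-oracle checks run at 1,000 motifs × 50 regions on 10 kb contigs
(overlap), 100 random slices (flanks), 50 points (k-means recovery), and
the full 104-group preset (batch) — sizes at which the brute-force
oracles are instant and the whole suite runs in well under a minute,
while still exercising every boundary case (contig edges, touching
intervals, spanning motifs, empty types).

## Known limitations

* Burdens are descriptive; no statistical testing of burden differences
  between groups, and no survival or outcome modelling, is included —
  the batch matrix is designed to feed such downstream analyses.
* Motif prediction from raw sequence is out of scope: the package
  consumes pre-computed motif libraries.
* Gene-level values depend on the supplied annotation's gene model (see
  above).
* K-means hyperparameters (k, scaling) materially change motif cluster
  memberships; defaults are sensible but results should be reported with
  their seed, k and feature set, which `glance()` exposes.
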