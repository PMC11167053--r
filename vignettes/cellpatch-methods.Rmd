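---
title: "Methods: patch-based segmentation orchestration and spatial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based segmentation orchestration and spatial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpatch)
```

## The problem

Image-based spatial omics assays — spatial transcriptomics platforms that
report individual transcript positions, and multiplex imaging platforms that
report tens of protein channels — produce slides too large for most
segmentation models to process whole, and their downstream questions (which
cell types sit near which tissue niches, what shapes do niches take) need
tooling that does not depend on the vendor. `cellpatch` implements the full
chain in a technology-invariant way: the same data model (a multi-channel
raster image with a micrometer pixel scale, an optional transcript point
table, polygonal cell boundaries) covers both families of platforms, and
every stage operates on that model only.

All coordinates live in one world frame: micrometers, origin at the image
top-left, x rightward along columns, y downward along rows. Pixel `(r, c)`
(0-based) has world center `(c * pixel_size, r * pixel_size)`. Pixel
membership in a polygon is decided at the pixel center with a half-open
rule (a center exactly on a left/top boundary counts, right/bottom does
not), which makes rasterization deterministic and partition-independent.

## Patching and conflict resolution

Segmentation runs on overlapping rectangular patches. Patch starts follow
`k * (patch_width - overlap)` per axis and the last patch is clamped to the
extent, so coverage is exact. The default overlap is 40 um — twice a
typical 20 um cell diameter — so that every cell is complete in at least
one patch. Patch rectangles are half-open (closed on their min edges, and
on the max edges of the last patch per axis): a transcript in an overlap
zone is deliberately assigned to *all* containing patches.

Because patches overlap, one physical cell can be segmented several times.
For every pair of cells from different patches whose bounding boxes
intersect, the intersection-over-min-area

\[ \mathrm{IOMA}(a, b) = \frac{|a \cap b|}{\min(|a|, |b|)} \in [0, 1] \]

decides the conflict: above 0.5 — the intersection exceeds half of the
smaller cell — the two boundaries are the same cell and are merged
(geometric union, repaired, largest part kept); at or below 0.5 both are
kept. Chains are closed transitively with a union-find, and the pass is
repeated until no cross-patch pair exceeds the threshold, which makes
resolution idempotent and patch-order invariant. Scores below 0.07 or
above 0.8 are the two unambiguous outcomes (clearly distinct cells,
clearly the same cell); the QC report bins all observed conflicts into
`good_distinct` / `ambiguous` / `good_duplicate` with those cutoffs. The
cutoffs describe resolution *quality*; they are not merge parameters.

The built-in segmenter (Gaussian smooth, fixed or Otsu threshold,
4-connected components, optional distance-transform watershed, minimum
area filter) exists so the orchestration is testable end to end; any model
that returns a label mask per patch window, or polygons in world
micrometers, plugs into the same contract. Label masks become polygons by
tracing the outer pixel edges exactly, so a label's polygon area equals
its pixel count times `pixel_size^2`; labels with holes are filled, since
segmented cells are modelled as simple polygons.

## Per-cell aggregation

Channel means are computed chunk by chunk: for each image chunk, the cells
whose bounding boxes intersect it are rasterized over their
bounding-box-within-chunk sub-array only, and per-cell sums and pixel
counts are accumulated. Chunks partition the pixel grid, so a cell
spanning several chunks accumulates every pixel exactly once; the result
is *identical* (not just close) to whole-image rasterization, which the
tests assert at 1e-9 relative tolerance over randomized chunk geometries.

Transcript counting splits points into square partitions (default 100 um)
and joins each partition only against the cells whose bounding boxes
intersect it. A point on a boundary shared by several cells goes to the
smallest cell id — an arbitrary but deterministic tie rule — and the
result is exactly invariant to the partition size, asserted against a
brute-force all-pairs join.

## Staining-based annotation

With `X` the N cells x P channels matrix of mean intensities, each channel
is variance-stabilized as

\[ X'_j = \operatorname{arcsinh}\!\left( \frac{X_j}{5\, Q(0.2, X_j)} \right) \]

where `Q(0.2, X_j)` is the channel's 20th percentile (linear-interpolation
quantile, the convention pinned for reproducibility). The transform is
strictly monotone per channel and exactly invariant to rescaling a channel
by any positive factor, since the percentile scales with the data — so
annotation does not depend on acquisition gain. When the 20th percentile
is zero (sparse channels), the divisor falls back to five times the
smallest positive value; an all-zero channel stays zero. Each cell is then
labelled by the marker channel with the highest preprocessed intensity
(ties to the lowest channel index; all-zero marker signal gives
`"unassigned"`), and `refine_by_clusters()` optionally relabels any
supplied clustering to its majority label.

## Hop-distance statistics

Cell centroids are triangulated (Delaunay); edges longer than 40 um are
pruned as they cannot correspond to a physical cell-cell contact. On the
pruned graph, the mean hop distance from category `g` to category `g'` is

\[ D(g, g') = \frac{1}{|\{i : C_i = g\}|} \sum_{i : C_i = g}
   \min_{j : C'_j = g'} d_{ij} \]

with `d_ij` the edge-count (hop) distance. For each `g'` one multi-source
breadth-first traversal from all `g'` nodes yields every `min_j d_ij` at
once; the tests assert exact equality with per-node BFS. The matrix is
asymmetric by construction (a rare population can be close to an abundant
one and not vice versa). Nodes with no finite path are excluded from the
mean and their counts reported, keeping the means finite and
interpretable. The four matrices (type-type, type-niche, niche-type,
niche-niche) combine into a colocalization network whose edge weight is
the inverse of the symmetrized mean distance, clamped at `eps = 0.5` hops
so categories fully nested in one another get a finite, maximal weight;
symmetrization is an interpretation choice (the directed matrices remain
available).

## Niche polygonization

Per-cell niche labels become geometry on the same graph: edges joining
different niches are dropped, the connected components are the niche
occurrences, and each component's triangulated region is bounded by its
border edges — the edges incident to exactly one retained triangle, the
standard boundary operator, which guarantees closed rings. Border edges
inherit an orientation from their (consistently counterclockwise) triangle,
so outer rings come out with positive signed area and holes negative;
a hole arises when one niche completely surrounds another. At a rare
"pinch" vertex (two lobes of a component touching at a point) rings are
split deterministically by the sharpest-turn rule and the extra outer
rings are kept as lobes, so the component's net area still equals the sum
of its triangle areas exactly — an invariant the tests check at 1e-6
relative tolerance.

Per niche we report occurrences, mean area `A`, perimeter `L` (net of
holes: exterior minus hole areas, exterior plus hole perimeters), the
roundness `R = 4 pi A / L^2` (1 for a disc, small for elongated shapes),
and cell density. Components below 5% of the niche's largest component
are discarded first, as they are typically artefacts of the upstream
niche clustering; density is computed after this filter, over the retained
geometry (the alternative — before filtering — differs negligibly and is
less consistent with the retained polygons). Components with fewer than
three cells have no triangle and are skipped with a warning.

## Visualizer bundle

The export writes an open, documented bundle: an image pyramid (level 0 at
full resolution, 2x2 mean downsamples until both dimensions fit one
1024 px tile, each level tiled 1024 x 1024, each level-0 tile produced
from exactly the source pixels it covers — the image's read counter makes
this contract testable); a transcript pyramid (250 um base tiles, tile
width doubling and point count quartered per level until one tile covers
the slide — the retained points are every fourth in stable input order,
i.e. `floor(n/4)` per level, a deterministic rule chosen because a random
subsample would not reproduce byte-identically); cell boundaries as an
N x 13 x 2 array (Douglas-Peucker simplification with a tolerance sweep
from 0.1 um doubling up to 20 times, then padding by repeating the last
vertex); and the counts table in gene-major compressed sparse form
(data / cell_index / gene_pointer, cell indices ascending within a gene)
plus per-category index/pointer arrays. Tiles and arrays are little-endian
binary blobs beside JSON metadata; `experiment.json` records presence
flags, shapes and the format constants. Everything except boundary
simplification and the higher pyramid levels round-trips exactly, and
re-running the export produces a byte-identical bundle.

## The synthetic tissue generator

`generate_tissue()` is first-class, tested code: it emulates a small
acquisition so every stage runs without external data. Cells are regular
24-gons (area and perimeter have closed forms, which the geometry tests
exploit) placed by rejection sampling with a minimum center spacing of
2.8 x radius — comfortably above the 2 x radius that guarantees
non-overlap, because tissue imaged at single-cell resolution is rarely
confluent and the gap gives any intensity-threshold segmenter a fair
fixture. Defaults: 120 cells of 5 um radius on a 512 x 512 px image at
0.5 um/px (a 256 um field), three cell types, a nuclear channel at 0.9
bright in every cell plus one marker channel per type (0.85 own-marker,
0.05 off-marker, 0.02 background, Gaussian noise sd 0.01, clamped to
[0, 1]), Poisson(30) transcripts per cell placed uniformly strictly inside
the polygon (90% signature gene), and 2e-4 background transcripts per
square um. Niches are spatial blocks (left/right halves by default), so
niche adjacency is known a priori for the hop-distance and polygonization
tests. One master seed fans out to per-component substreams, so the same
seed reproduces the image, transcripts and ground truth byte for byte.

What the generator does *not* emulate — optics (point-spread blur,
autofluorescence), irregular cell shapes, confluent tissue, segmentation
errors of real models, transcript density gradients — bounds what the
passing tests show: they validate the orchestration, the conflict
resolution, the aggregation algebra and the statistics exactly, not the
biological performance of any particular segmenter on real tissue.

## Numerical choices and limitations

* Polygon booleans use `polyclip` (integer-snapped clipping); areas are
  shoelace sums. IOMA values in tests are asserted against hand-computed
  rectangle overlaps.
* Invalid polygons are repaired by resolving self-intersections with the
  non-zero fill rule and keeping the largest part.
* Duplicate centroids before triangulation are perturbed deterministically
  by ~1e-9 um (no RNG involved) with a warning; two points give a single
  edge iff within the cutoff; three or more collinear points get the
  consecutive-neighbour chain, which is the Delaunay limit.
* Degenerate inputs (empty collections, blank patches, all-zero channels,
  empty transcript tables) return empty results rather than errors, except
  where the contract demands a validation error (negative intensities,
  zero-area polygons, overlap >= patch width).
* Problem sizes in the test-suite fixtures (tissues of 30-120 cells on
  256-512 px images, graphs up to 500 nodes, 20-50 randomized replicates
  per oracle check) were chosen so each oracle comparison is exhaustive at
  a scale where the brute-force reference is itself trustworthy.
* The pipeline holds each image in memory; chunking bounds the *working
  set* of aggregation and tile export and proves the algebra is
  chunk-local, but no out-of-core scheduler is included.
* The CLI is a thin wrapper over the exported functions; the bundle is an
  open layout, not a byte-compatible copy of any vendor's format.
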