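---
title: "Comparing multiple clustering results with clustersets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multiple clustering results with clustersets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustersets)
```

## The problem

Cluster analysis of expression data is rarely a single computation.
Different algorithms — and the same algorithm under different parameter
settings or seeds — partition the same genes differently, and the
analyst's real question is usually comparative: which genes travel
together across *every* reasonable clustering, which results resemble
each other, and which run best isolates the gene set of interest.
`clustersets` implements the computational core of that workflow:
generating partitions with several algorithm families, quantifying
similarity between partitions, extracting the item sets that are stable
across partitions, assigning system-wide colors to clusters so that
similar clusters look similar everywhere, and laying out and rendering
the comparison as static SVG views.

## Pair-counting similarity between partitions

Two clustering results $A$ and $B$ over the same items are compared by
their co-clustered pair sets. Let $P_A$ be the set of unordered item
pairs sharing a cluster in $A$, likewise $P_B$. Then

$$\mathrm{precision} = \frac{|P_A \cap P_B|}{|P_A|},\qquad
  \mathrm{recall} = \frac{|P_A \cap P_B|}{|P_B|},\qquad
  F = \frac{2\,\mathrm{pr}\,\mathrm{rc}}{\mathrm{pr}+\mathrm{rc}},$$

the harmonic mean being symmetric in the two results. $F = 1$ exactly
when the partitions coincide up to label renaming, because equal pair
sets determine equal partitions. Two degenerate cases need a
convention: when both partitions are all-singletons both pair sets are
empty and we define $F = 1$ (identical structure); when exactly one is
empty, $F = 0$. These choices preserve the "1 iff identical" property.
Which result supplies precision and which recall is irrelevant to $F$.

Items a density-based run leaves unassigned are carried as a single
*noise cluster* rather than as singletons — otherwise every unclustered
item would form its own stable group and the comparison views would
shatter. The noise cluster's internal pairs count toward the pair sets
by default; `include_noise = FALSE` excludes them, since either reading
of a partial clustering is defensible.

`f_measure()` is computed from the label contingency table
($\sum_{ij}\binom{n_{ij}}{2}$ for agreed pairs), and the test suite
checks it against an independent oracle that literally enumerates and
intersects the pair sets — exhaustively over **all** pairs of set
partitions of up to 6 items, plus random partitions up to $n = 50$.

## Stable groups: the meet of the partitions

A *stable group* is a maximal set of items that share a cluster in
every selected result — a block of the meet (greatest common
refinement) of the partitions. `stable_groups()` computes it by
grouping items on their *signature*, the tuple of cluster labels across
the source results; the brute-force oracle in the tests instead groups
by scanning cluster membership lists. Groups are ordered by descending
size then signature. Size filtering (`filter_groups()`) only toggles a
`visible` flag: the partition itself is never changed, and layouts
leave proportional blank space for hidden bands so bar widths remain
meaningful.

```{r stable}
ds <- planted_matrix(200, 8, 4, separation = 10, noise_sd = 1, seed = 1)
r1 <- run_kmeans(ds$matrix, 4, seed = 1)
r2 <- run_kmeans(ds$matrix, 5, seed = 2)
r3 <- cut_by_similarity(hac_items(ds$matrix), 0.5)
sgs <- stable_groups(list(r1, r2, r3))
sgs
group_histogram(sgs)
```

## Clustering runners

The package runs four algorithm families, all seed-deterministic, and
imports externally produced assignment tables (`import_assignments()`)
so results from any other tool can join the comparison.

* **k-means** (`run_kmeans()`): Lloyd iterations from greedy
  farthest-point seeding (the first center drawn from the seeded RNG,
  each next center the point farthest from the chosen ones). One call
  is one run; re-runs under other seeds are registered as separate
  results, which is how the non-determinism of k-means is surfaced
  rather than hidden. The `correlation` metric standardizes each row to
  mean 0 and unit norm and then runs Euclidean k-means: squared
  Euclidean distance between standardized rows is monotone in
  $1 - r_{\mathrm{Pearson}}$, and the arithmetic-mean centroid update
  remains valid, which a naive correlation distance inside Lloyd's loop
  would break.
* **HAC** (`hac_items()`, via `stats::hclust`): average linkage by
  default (complete and single selectable). Merge heights are exposed
  on a *similarity* scale so a minimum-similarity bar can cut the tree
  (`cut_by_similarity()`): for the correlation metric similarity is
  $1 - d \in [-1, 1]$; for Euclidean distances it is $1 - h/h_{\max}$,
  a normalized $[0,1]$ scale (Euclidean distances have no natural
  similarity unit). Leaf order is made deterministic by placing, at
  every merge, the subtree containing the smaller original row index on
  the left.
* **SOM** (`run_som()`): online training on a hexagonal grid (odd rows
  offset by half a cell), Gaussian neighborhood, radius decaying
  linearly from half the larger grid dimension to 0.2 and learning rate
  from 0.3 to 0.01 over 30 epochs, codebook initialized by
  farthest-point sampling of data rows. Empty cells stay in the grid
  but are excluded from the partition view.
* **OPTICS** (`run_optics()`): the standard ordering/reachability
  algorithm with Euclidean distances; the $\varepsilon$-neighborhood
  includes the point itself, so with `min_pts = 2` the core distance is
  the nearest-neighbor distance. Start points are taken in row order
  and seed-queue ties break toward the smaller row index, making the
  ordering fully deterministic — which is what lets the tests demand
  *exact* agreement with an independently written reference
  implementation. Cluster extraction (`extract_optics_clusters()`) is a
  horizontal cut of the reachability plot: maximal runs with
  reachability at most the threshold, each run extended by the
  valley-opening item before it, kept if at least `min_pts` items;
  everything else joins the noise cluster. The start/end positions of
  each cluster are retained for the reachability renderer's horizontal
  bars. We chose the horizontal-cut rule over steepness-based
  extraction because it is the rule a threshold bar under the plot
  actually expresses.

A `session_registry()` accumulates results and
`parameter_counts()` aggregates how often each algorithm/setting was
used; the canonical setting excludes the seed, so repeated runs of a
non-deterministic algorithm under one setting accumulate in one count.

## Tree Colors for clusters

To make cluster similarity visible across all views, every cluster of
every result is a leaf in one global hierarchy (`build_cluster_tree()`):
HAC, average linkage, distance $1 -$ Pearson correlation between mean
expression profiles (a flat, zero-variance profile has undefined
correlation and is treated as unrelated, correlation 0, with a
warning). `assign_colors()` then subdivides a hue range down this tree.

At each node the interval splits into two slots proportional to the
children's leaf counts, and each child keeps the central
`1 - reserve_fraction` of its slot (default reserve 0.5), leaving
buffers on *both* sides of every subtree — including across the wrap
of the full $[0,360)$ circle. A leaf's hue is its interval midpoint;
chroma falls (80 to 45) and luminance rises (45 to 80) linearly with
depth, capped at depth 4, and HCL coordinates are converted to sRGB
with gamut clipping via `grDevices::hcl()`.

The two-sided buffer is a deliberate design choice over the more
obvious single central gap. With one central gap the within-subtree
hue spread can exceed the gap to the sibling subtree (a leaf near the
gap ends up closer in hue to the sibling than to far members of its
own subtree), destroying the reading "similar hue = similar cluster".
With half-slot buffers, the within-subtree spread is bounded by the
buffer to anything outside on balanced hierarchies, and the property
is asserted on random balanced trees in the tests. Subtrees merged at
distance ~0 (identical clusters re-found by different runs) are not
subdivided at all: their leaves share one interval and therefore one
identical hue.

## Parallel-sets layout and crossing minimization

The comparison view stacks one row of bars per result (bar width
proportional to cluster size, a small gap between bars so adjacent
same-hued clusters stay distinguishable) and routes each visible stable
group as a band with one segment per row, width proportional to group
size. Row order comes from `order_results()` — greedy chaining from the
most similar pair, appending at whichever chain end has the most
similar remaining result, or the leaf order of the results dendrogram —
and vertical spacing between adjacent rows is proportional to their
dissimilarity $1 - F$, floored at 15% of the largest spacing so that
identical results remain visually separated. Widths use one scale per
row, $(W - \text{gaps})/n$, so bar widths plus gaps tile the full
layout width exactly (checked to $10^{-9}$).

Visual clutter is the crossing count: for each adjacent row pair, the
number of band pairs whose segment-midpoint order differs between the
rows (`count_crossings()`). Rearrangement splits into the two
operations of the interactive workflow:

* `rearrange_bars()` reorders the bars in each row (barycenter sweeps
  top-down then bottom-up, keyed by the mean midpoint of each bar's
  groups in the adjacent row, plus a greedy adjacent-transposition
  polish). Rows given a manual bar order at build time are frozen.
* `rearrange_bands()` reorders segments within bars, bars fixed
  (barycenter against the previous row, first row against the next,
  ties broken by group signature, then a swap-with-relaxation polish in
  which a candidate swap is judged after the other rows re-sort).

Both operations are exact on small instances: when the joint order
space has at most 5000 configurations they enumerate it and take the
minimum-crossing configuration, so tiny layouts are provably optimal;
beyond that budget the barycenter machinery takes over (the polish is
quadratic in the band count and disengages above 15 groups). Both
operations end with a never-worsen guard, so rearranged layouts never
have more crossings than their input, and both are idempotent. Global
optimization (e.g. ILP) is out of scope by design.

`render_parallel_sets()` draws bars in their Tree Colors, bands as
vertical-gradient ribbons between their end clusters' colors at
reduced opacity (one ribbon per row gap plus one in-bar segment
rectangle per row), an optional *common-angle* mode in which every
ribbon becomes three runs — vertical, slanted, vertical — sharing one
global slant angle sized so the widest band's slanted run fits 80% of
the row gap (defeating the line-width illusion when comparing band
widths), hover-style highlighting by dimming all but a target cluster's
or group's bands, and the stable-group size histogram with the current
filter range underneath.

## Overviews and per-result views

`fdl_overview()` places one node per result by deterministic gradient
descent on the stress $\sum_{ij}(d_{ij} - L_{ij})^2$ with rest lengths
$L_{ij} = 0.1 + (1 - F_{ij})$ from seeded random positions (500
iterations, decaying step). All pairs participate in the layout; edges
are then kept only above the similarity threshold (default 0.3), drawn
with stroke width proportional to $F$. Node radius shrinks as
$1/\sqrt{\text{results}}$ and each node carries a pie of its cluster
sizes in the global colors. `results_dendrogram()` applies the same
HAC conventions as item clustering to the $1 - F$ matrix.
Per-result views: dendrogram + heatmap with the minimum similarity bar
and a miniature whole-matrix overview; per-result cluster graph (FDL of
clusters, rectangle area proportional to size, edges weighted by
centroid correlation); SOM hex grid with cell background intensity
proportional to cluster size and a mean-profile glyph; OPTICS
reachability plot with infinite bars capped at 1.1 times the maximum
finite reachability, horizontal cluster span bars beneath, and a
cluster-colored parallel-coordinates panel of member profiles. Every
renderer is a pure function emitting SVG 1.1 text.

## Synthetic data

`planted_matrix()` generates the study substrate: `k` Gaussian cluster
profiles around centroids on an axis-aligned simplex scaled so any two
centroids are at least `separation * noise_sd` apart (so `separation`
is the center spacing in noise-SD units), balanced cluster sizes, an
optional fraction of uniform scatter rows labelled as the planted noise
cluster, and full bit-reproducibility per seed. It emulates the shape
of normalized expression matrices — hundreds to thousands of rows, a
handful to ~19 condition columns — but deliberately not their
distributional detail: no negative-binomial counts, no library-size or
batch structure, no correlated noise. Passing recovery tests on this
generator therefore demonstrates that the pipeline's mathematics and
determinism are right, not that any particular algorithm will dominate
on real RNA-seq data. `perturb_partition()` reassigns exactly
$\lfloor f n\rfloor$ random items to random other clusters, producing
the families of near-duplicate results used to validate that $F$
degrades monotonically with the flip fraction.

Problem sizes used in the shipped checks: partition-pair enumeration is
exhaustive to $n = 6$ items (about 21,000 pairs) with random sampling
at $n = 7$–$50$; the meet-partition and OPTICS oracles run on hundreds
of random instances at $n \le 50$/$60$; recovery runs use $n = 600$
items, 8 conditions, $k = 4$, separation 10, over 5 seeds.

## Numerical and degenerate-input conventions

* Matrices must be fully finite; missing values are rejected, not
  imputed. Filters that would empty a matrix are errors.
* Ratio/fold-change derivation uses an explicit pseudocount (default
  1): `log2fc = log2((a + c)/(b + c))`; a zero denominator with a zero
  pseudocount is an error. Range filters are closed on both ends, and
  abundance thresholds apply to the original measurement columns, not
  to derived ratio columns.
* Delimiter auto-detection: a tab in the header line means
  tab-delimited, otherwise comma.
* Comparisons over differing item sets are hard errors naming the
  symmetric difference; `restrict = TRUE` opts into
  intersection-restricted comparison for imported results.
* Centroid correlations with zero variance are 0 (with a warning);
  zero-variance rows under the correlation metric are treated as
  unrelated (distance 1) in hierarchies.
* All seeded operations (generation, k-means, SOM, layout, CLI runs)
  are bit-reproducible given the same seed and input.

## Command line

The installed `exec/clustersets` script exposes the workflow as
subcommands (`synth`, `derive`, `filter`, `cluster`, `import`,
`compare`, `render`), all thin wrappers over the exported functions
with `--seed` wherever randomness exists; sessions persist as a single
JSON file with inline assignments so they remain portable. Rendering
emits SVG; rasterization is intentionally not bundled.

## Limitations

* The barycenter heuristics are not globally optimal beyond the
  exhaustive-search budget; they only guarantee never-worsen.
* Hue-distance monotonicity is guaranteed for balanced hierarchies;
  strongly skewed hierarchies keep interval nesting and sibling
  disjointness but the pointwise hue-distance ordering may weaken.
* The SOM is a classic online implementation intended for the small
  grids used in expression practice, not for large-map workloads.
* Interactivity (brushing, dragging, animation, semantic zoom) is out
  of scope; the renderers produce static documents.
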