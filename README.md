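# clustersets

Comparison and visualization of multiple clustering results of
expression-style datasets.

Cluster analysis of gene expression data is exploratory: the same
matrix gets clustered with several algorithms, parameter settings and
seeds, and the scientifically interesting objects are *relations
between the runs* — which results agree, which genes stay together in
every run, which single run best isolates a gene set of interest.
`clustersets` provides that comparison layer for R users: partition
runners (k-means, hierarchical with a minimum-similarity-bar cut,
self-organizing maps, OPTICS, plus import of assignments from any
external tool), the comparison mathematics, a system-wide cluster
coloring, a crossing-minimized parallel-sets layout, and static SVG
renderers for every view, all seed-deterministic and scriptable.

## The core quantities

**Pair-counting F-measure.** Two partitions $A$, $B$ of the same items
are compared through their co-clustered pair sets $P_A$, $P_B$
(unordered item pairs sharing a cluster). With
$\mathrm{pr} = |P_A \cap P_B|/|P_A|$ and
$\mathrm{rc} = |P_A \cap P_B|/|P_B|$,

$$F(A,B) = \frac{2\,\mathrm{pr}\,\mathrm{rc}}{\mathrm{pr}+\mathrm{rc}}
\in [0,1],$$

symmetric, and equal to 1 exactly when the partitions coincide up to
label renaming. Unassigned items from density-based runs form a single
noise cluster whose pairs count by default (`include_noise = FALSE` to
exclude).

**Stable groups.** A stable group is a maximal item set co-clustered in
*every* selected result — a block of the meet (greatest common
refinement) of the partitions, computed by grouping items on their
label signature across results. Bands in the parallel-sets view are
stable groups; band width encodes group size.

**Tree Colors.** All clusters of all results are leaves of one HAC
hierarchy (distance = 1 − Pearson correlation of centroid profiles); a
hue range is recursively subdivided down that tree (leaf-proportional
slots, central-fraction buffers, chroma/luminance varying with depth),
so similar clusters get similar colors in every view.

**Crossing minimization.** Rows (results) are seriated by similarity;
bar and band orders are rearranged by barycenter sweeps with a
local-search polish — and by exhaustive search when the instance is
small enough to enumerate — never increasing the crossing count.

## Worked example

```r
library(clustersets)

# planted-structure fixture: 300 genes x 8 conditions, 4 clusters,
# centroids 10 noise-SDs apart
ds <- planted_matrix(300, 8, 4, separation = 10, noise_sd = 1, seed = 11)

r1 <- run_kmeans(ds$matrix, 4, seed = 1)
r2 <- run_kmeans(ds$matrix, 5, seed = 2)
r3 <- cut_by_similarity(hac_items(ds$matrix), 0.5)
r4 <- extract_optics_clusters(run_optics(ds$matrix, min_pts = 5), 5)
res <- list(r1, r2, r3, r4)

round(unclass(similarity_matrix(res)), 3)
#>                              KMeans(k=4,...) KMeans(k=5,...) HAC(...) OPTICS(...)
#> KMeans(k=4,euclidean,seed=1)           1.000           0.933    1.000       1.000
#> KMeans(k=5,euclidean,seed=2)           0.933           1.000    0.933       0.933
#> HAC(euclidean,average,s=0.5)           1.000           0.933    1.000       1.000
#> OPTICS(min_pts=5,r=5)                  1.000           0.933    1.000       1.000

f_measure(r1, ds$truth)
#> [1] 1
```

Three of the four runs recover the planted partition exactly
(pairwise $F = 1$); the $k = 5$ run splits one planted cluster, which
costs it ~0.067 of pair-level agreement against everything else.

```r
sgs <- stable_groups(res)
sgs
#> <stable_group_set> 5 groups over 300 items from 4 results (5 visible)
group_histogram(sgs)
#> 34 41 75
#>  1  1  3
```

The meet of the four partitions has 5 stable groups: the three intact
planted clusters (75 genes each) and the two halves (34 + 41) of the
cluster that `k = 5` split.

```r
colors <- assign_colors(build_cluster_tree(res, ds$matrix))
head(colors$colors[, c("cluster_id", "hue", "hex")], 4)
#>                         cluster_id       hue     hex
#> 1 KMeans(k=4,euclidean,seed=1)::C1  70.14706 #D8C58C
#> 2 KMeans(k=4,euclidean,seed=1)::C2 254.11765 #7797DA
#> 3 KMeans(k=4,euclidean,seed=1)::C3 121.76471 #64A74F
#> 4 KMeans(k=4,euclidean,seed=1)::C4 296.47059 #BE80D1

lay <- build_layout(res, sgs, colors = colors,
                    row_order = order_results(similarity_matrix(res)))
count_crossings(lay)
#> [1] 11
lay <- rearrange_bands(rearrange_bars(lay))
count_crossings(lay)
#> [1] 0
write_svg(render_parallel_sets(lay), "parallel_sets.svg")
```

Rearrangement removes all 11 band crossings of the size-sorted initial
layout; the SVG shows four rows of bars (one per result) with the five
stable-group bands flowing straight through.

Other views: `render_fdl(fdl_overview(sm, results = res, colors =
colors))` (force-directed map of results),
`render_results_dendrogram()`, `render_parameter_counts()`,
`render_reachability()` (OPTICS), `render_som()`,
`render_cluster_graph()`, `render_dendro_heatmap()`.

## Command line

The installed `exec/clustersets` script wraps the same functions:

```sh
clustersets synth --out m.csv --n 600 --conditions 8 --k 4 \
    --separation 10 --seed 1
clustersets cluster kmeans --matrix m.csv --session s.json --k 4 --seed 1
clustersets cluster optics --matrix m.csv --session s.json \
    --min-pts 5 --r-threshold 5
clustersets compare --session s.json --out-similarity sim.csv \
    --out-groups groups.json
clustersets render parallel-sets --session s.json --matrix m.csv \
    --out view.svg
```

Every subcommand takes `--seed` wherever randomness exists; identical
invocations produce byte-identical outputs.

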