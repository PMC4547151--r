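Package: clustersets
Title: Comparison and Visualization of Multiple Clustering Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for generating, comparing and rendering multiple
    clustering results of expression-style datasets. Implements
    pair-counting F-measure similarity between partitions, stable-group
    (meet-partition) extraction, a global cluster hierarchy with
    recursive hue-range ("Tree Colors") color assignment,
    crossing-minimizing parallel-sets arrangement, and static SVG
    renderings of overview and per-result views (force-directed result
    maps, results dendrograms, OPTICS reachability plots, SOM grids,
    dendrogram-plus-heatmap panels). Includes k-means, hierarchical,
    self-organizing-map and OPTICS clustering runners with a session
    registry, CSV import/export of expression matrices and cluster
    assignments, and a planted-cluster synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
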