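fixture_session <- function(seed = 1) {
  ds <- planted_matrix(60, 6, 3, separation = 10, noise_sd = 1,
                       seed = seed)
  res <- list(run_kmeans(ds$matrix, 3, seed = 1),
              run_kmeans(ds$matrix, 4, seed = 2),
              cut_by_similarity(hac_items(ds$matrix), 0.5))
  list(ds = ds, res = res, sm = similarity_matrix(res),
       colors = assign_colors(build_cluster_tree(res, ds$matrix)))
}

test_that("the force-directed overview is deterministic and distance-faithful", {
  sm <- matrix(c(1, .9, .1,
                 .9, 1, .9,
                 .1, .9, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(sm) <- c("similarity_matrix", class(sm))
  g1 <- fdl_overview(sm, seed = 4)
  g2 <- fdl_overview(sm, seed = 4)
  expect_identical(g1$positions, g2$positions)
  d <- as.matrix(dist(g1$positions))
  expect_gt(d["A", "C"], d["A", "B"])
  expect_gt(d["A", "C"], d["B", "C"])
  # edge filtering happens after layout
  expect_equal(nrow(fdl_overview(sm, threshold = 1)$edges), 0L)
  expect_equal(nrow(fdl_overview(sm, threshold = 0.5)$edges), 2L)
  # single result: one node at the origin, no edges
  sm1 <- sm[1, 1, drop = FALSE]
  class(sm1) <- c("similarity_matrix", class(sm1))
  g3 <- fdl_overview(sm1)
  expect_equal(unname(g3$positions), matrix(0, 1, 2))
  expect_equal(nrow(g3$edges), 0L)
})

test_that("fdl edge set equals the supra-threshold pair set", {
  fx <- fixture_session()
  for (thr in c(0, 0.3, 0.8)) {
    g <- fdl_overview(fx$sm, threshold = thr)
    expected <- 0L
    ids <- rownames(fx$sm)
    for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids)))
      if (fx$sm[i, j] > thr) expected <- expected + 1L
    expect_equal(nrow(g$edges), expected)
    if (nrow(g$edges)) expect_true(all(g$edges$weight > thr))
  }
})

test_that("the results dendrogram merges the most similar results first", {
  sm <- matrix(c(1, .9, .5,
                 .9, 1, .5,
                 .5, .5, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(sm) <- c("similarity_matrix", class(sm))
  d <- results_dendrogram(sm)
  expect_setequal(d$hclust$merge[1, ], c(-1, -2))  # A,B first
  expect_equal(d$hclust$height[1], 1 - 0.9, tolerance = 1e-12)
  # identical results merge at distance 0
  sm2 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  class(sm2) <- c("similarity_matrix", class(sm2))
  expect_equal(results_dendrogram(sm2)$hclust$height, 0)
  expect_error(results_dendrogram(sm2[1, 1, drop = FALSE]), "at least 2")
})

test_that("every renderer emits well-formed SVG", {
  fx <- fixture_session()
  sgs <- stable_groups(fx$res)
  lay <- build_layout(fx$res, sgs, colors = fx$colors,
                      row_order = order_results(fx$sm))
  lay <- rearrange_bands(rearrange_bars(lay))
  svgs <- list(
    parallel_sets = render_parallel_sets(lay),
    parallel_sets_ca = render_parallel_sets(lay, common_angle = TRUE),
    fdl = render_fdl(fdl_overview(fx$sm, results = fx$res,
                                  colors = fx$colors)),
    dendro = render_results_dendrogram(results_dendrogram(fx$sm),
                                       results = fx$res,
                                       colors = fx$colors),
    som = render_som(run_som(fx$ds$matrix, 2, 2, seed = 1), fx$ds$matrix),
    cluster_graph = render_cluster_graph(fx$res[[1]], fx$ds$matrix,
                                         fx$colors, seed = 1),
    heatmap = render_dendro_heatmap(hac_items(fx$ds$matrix),
                                    fx$ds$matrix, cut = 0.5))
  o <- run_optics(fx$ds$matrix, min_pts = 3)
  cr <- extract_optics_clusters(o, 5)
  svgs$reach <- render_reachability(o, cr, fx$colors, fx$ds$matrix)
  reg <- session_registry()
  for (r in fx$res) reg <- register(reg, r)
  svgs$params <- render_parameter_counts(parameter_counts(reg))
  for (nm in names(svgs)) {
    doc <- xml2::read_xml(svgs[[nm]])
    expect_equal(xml2::xml_name(doc), "svg")
  }
})

test_that("renderers are pure functions of their inputs", {
  fx <- fixture_session()
  g <- fdl_overview(fx$sm, seed = 9)
  expect_identical(render_fdl(g), render_fdl(g))
  lay <- build_layout(fx$res, stable_groups(fx$res), colors = fx$colors)
  expect_identical(render_parallel_sets(lay), render_parallel_sets(lay))
})

test_that("parallel-sets bands follow the documented element counts", {
  ids <- sprintf("i%d", 1:10)
  res <- lapply(c("a", "b", "c"), function(id)
    cr_from_labels(rep(c("X", "Y"), each = 5), id, ids))
  lay <- build_layout(res, stable_groups(res))
  count_el <- function(svg, cls)
    length(xml2::xml_find_all(xml2::read_xml(svg),
                              sprintf(".//*[@class='%s']", cls)))
  plain <- render_parallel_sets(lay)
  # 2 groups x (3 rows - 1) ribbons; 2 groups x 3 rows segment rects
  expect_equal(count_el(plain, "band"), 2 * 2)
  expect_equal(count_el(plain, "band-seg"), 2 * 3)
  ca <- render_parallel_sets(lay, common_angle = TRUE)
  expect_equal(count_el(ca, "band"), 2 * 2 * 3)  # 3 runs per gap
  # bar fills pass the assigned colors through verbatim
  set.seed(2)
  mref <- tiny_matrix(matrix(rnorm(40), 10), ids = ids)
  colors <- assign_colors(build_cluster_tree(res, mref))
  lay2 <- build_layout(res, stable_groups(res), colors = colors)
  svg <- render_parallel_sets(lay2)
  doc <- xml2::read_xml(svg)
  fills <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//*[@class='bar']"), "fill")
  expect_true(all(fills %in% colors$colors$hex))
  # empty visible set still renders bars
  sgs0 <- filter_groups(stable_groups(res), min_size = 100)
  lay0 <- build_layout(res, sgs0)
  svg0 <- render_parallel_sets(lay0)
  expect_equal(count_el(svg0, "band"), 0)
  expect_gt(count_el(svg0, "bar"), 0)
})

test_that("reachability rendering shows cluster spans and capped bars", {
  ds <- planted_matrix(40, 4, 2, separation = 12, seed = 21)
  o <- run_optics(ds$matrix, min_pts = 3)
  cr <- extract_optics_clusters(o, 6)
  svg <- render_reachability(o, cr, m = ds$matrix)
  doc <- xml2::read_xml(svg)
  bars <- xml2::xml_find_all(doc, ".//*[@class='cluster-bar']")
  expect_equal(length(bars),
               length(setdiff(names(cr$clusters), "(noise)")))
  # mismatched inputs are rejected
  other <- extract_optics_clusters(run_optics(
    planted_matrix(30, 4, 2, seed = 5)$matrix, min_pts = 3), 6)
  expect_error(render_reachability(o, other, m = ds$matrix),
               "does not match")
})

test_that("proportionality contracts hold in parameter and SOM views", {
  counts <- data.frame(algorithm = c("kmeans", "kmeans"),
                       setting = c("k=9, metric=euclidean",
                                   "k=11, metric=euclidean"),
                       count = c(3L, 1L))
  svg <- render_parameter_counts(counts)
  doc <- xml2::read_xml(svg)
  hs <- as.numeric(xml2::xml_attr(
    xml2::xml_find_all(doc, ".//*[@class='count-bar']"), "height"))
  expect_equal(max(hs) / min(hs), 3, tolerance = 1e-4)
  # SOM 1x1: a single full-intensity hexagon
  ds <- planted_matrix(20, 4, 2, seed = 8)
  svg2 <- render_som(run_som(ds$matrix, 1, 1, seed = 1), ds$matrix)
  cells <- xml2::xml_find_all(xml2::read_xml(svg2),
                              ".//*[@class='cell']")
  expect_equal(length(cells), 1L)
  expect_equal(as.integer(xml2::xml_attr(cells, "data-size")), 20L)
})

test_that("dendro-heatmap row order equals the dendrogram leaf order", {
  ds <- planted_matrix(15, 5, 3, separation = 8, seed = 13)
  h <- hac_items(ds$matrix)
  svg <- render_dendro_heatmap(h, ds$matrix)
  expect_true(grepl("^<svg", svg))
  # heatmap cells exist for every item x condition
  doc <- xml2::read_xml(svg)
  cells <- xml2::xml_find_all(doc, ".//*[@class='hm']")
  expect_equal(length(cells), 15L * 5L)
})
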