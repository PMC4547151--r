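#' Collect all clusters of several results, with centroids
#'
#' Helper used by the global cluster hierarchy and by renderers: one row
#' per cluster of every result, with its mean profile.
#'
#' @param results list of `clustering_result`s.
#' @param m the `expr_matrix` the results were computed on.
#' @return List with `info` (data.frame: `cluster_id`
#'   (`result_id::label`), `result_id`, `label`, `size`, `is_noise`) and
#'   `centroids` (clusters x conditions matrix).
#' @export
all_clusters <- function(results, m) {
  stopifnot(length(results) >= 1L, inherits(m, "expr_matrix"))
  rows <- list(); cents <- list()
  for (r in results) {
    stopifnot(inherits(r, "clustering_result"))
    for (label in names(r$clusters)) {
      id <- paste0(r$result_id, "::", label)
      rows[[id]] <- data.frame(cluster_id = id, result_id = r$result_id,
                               label = label,
                               size = length(r$clusters[[label]]),
                               is_noise = identical(label, r$noise_label),
                               stringsAsFactors = FALSE)
      cents[[id]] <- cluster_centroid(r, label, m)
    }
  }
  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  centroids <- do.call(rbind, cents)
  list(info = info, centroids = centroids)
}

#' Global hierarchy over all clusters of all results
#'
#' Hierarchically clusters the clusters themselves (HAC, average linkage
#' by default) with distance `1 - Pearson correlation` between centroid
#' profiles, producing the tree that drives the Tree Colors assignment so
#' that similar clusters — wherever they come from — receive similar
#' colors. A zero-variance centroid has undefined correlation and is
#' treated as unrelated (distance 1) to everything.
#'
#' @param results list of `clustering_result`s.
#' @param m the `expr_matrix` the results were computed on.
#' @param linkage linkage method for [stats::hclust()].
#' @return An object of class `cluster_tree`: `info` and `centroids` as in
#'   [all_clusters()] plus the `hclust` tree (NULL for a single cluster).
#' @export
build_cluster_tree <- function(results, m, linkage = "average") {
  ac <- all_clusters(results, m)
  k <- nrow(ac$info)
  if (ncol(ac$centroids) < 2L)
    stop("need at least 2 conditions to correlate centroids",
         call. = FALSE)
  hc <- NULL
  if (k >= 2L) {
    cors <- suppressWarnings(stats::cor(t(ac$centroids)))
    cors[is.na(cors)] <- 0
    d <- 1 - cors
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    hc$labels <- ac$info$cluster_id
    hc <- reorder_hclust(hc)
  }
  structure(list(info = ac$info, centroids = ac$centroids, hclust = hc),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d clusters from %d results\n",
              nrow(x$info), length(unique(x$info$result_id))))
  invisible(x)
}

#' Tree Colors assignment over a cluster hierarchy
#'
#' Recursive hue-range subdivision: the root owns the full hue range; at
#' each internal node the interval is divided into two slots
#' proportional to the children's leaf counts, and each child receives
#' the central `1 - reserve_fraction` of its slot, the rest acting as a
#' buffer on both sides. Nearby leaves therefore end up with nearby
#' hues, large subtrees keep wide, discriminable ranges, and — because
#' buffers accumulate on *both* sides of every slot, including across
#' the wrap of a full-circle range — the circular hue distance between
#' two leaves grows as their common ancestor gets shallower. (A single
#' central gap, the more obvious construction, breaks that ordering:
#' leaves near the gap sit closer to the sibling subtree than to far
#' members of their own.) A leaf's hue is its interval midpoint. Chroma
#' falls and luminance rises linearly with depth (capped at depth 4),
#' and hue/chroma/luminance coordinates are converted to sRGB with gamut
#' clipping. Subtrees merged at distance ~0 (e.g. identical clusters
#' re-discovered by different runs) are not subdivided: all their leaves
#' share one interval and hence one hue.
#'
#' @param tree a `cluster_tree` from [build_cluster_tree()].
#' @param hue_range half-open hue interval in degrees, default `[0, 360)`.
#' @param reserve_fraction fraction of each child's slot reserved as
#'   buffer, in `[0, 1)`; at 0.5 within-subtree hue spread is bounded by
#'   the gap to any other subtree on balanced trees.
#' @param chroma_ramp chroma at depth 0 and at depth >= 4.
#' @param luminance_ramp luminance at depth 0 and at depth >= 4.
#' @return An object of class `color_assignment`: `colors` (data.frame
#'   per cluster: `cluster_id`, `result_id`, `label`, `h_lo`, `h_hi`,
#'   `hue`, `chroma`, `luminance`, `hex`) and `nodes` (per tree node:
#'   interval and depth, for structural checks).
#' @export
assign_colors <- function(tree, hue_range = c(0, 360),
                          reserve_fraction = 0.5,
                          chroma_ramp = c(80, 45),
                          luminance_ramp = c(45, 80)) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (diff(hue_range) <= 0) stop("degenerate hue range", call. = FALSE)
  if (reserve_fraction < 0 || reserve_fraction >= 1)
    stop("reserve_fraction must be in [0, 1)", call. = FALSE)
  k <- nrow(tree$info)
  leaf <- data.frame(h_lo = rep(NA_real_, k), h_hi = NA_real_,
                     hue = NA_real_, depth = NA_integer_)
  nodes <- list()

  if (k == 1L) {
    leaf[1L, ] <- list(hue_range[1L], hue_range[2L], mean(hue_range), 0L)
  } else {
    hc <- tree$hclust
    nmerge <- nrow(hc$merge)
    counts <- integer(nmerge)
    cnt <- function(v) if (v < 0L) 1L else counts[v]
    for (i in seq_len(nmerge))
      counts[i] <- cnt(hc$merge[i, 1L]) + cnt(hc$merge[i, 2L])
    fill_leaves <- function(v, lo, hi, hue, depth) {
      if (v < 0L) {
        leaf[-v, ] <<- list(lo, hi, hue, depth)
      } else {
        fill_leaves(hc$merge[v, 1L], lo, hi, hue, depth)
        fill_leaves(hc$merge[v, 2L], lo, hi, hue, depth)
      }
    }
    recurse <- function(v, lo, hi, depth) {
      nodes[[length(nodes) + 1L]] <<-
        data.frame(node = v, h_lo = lo, h_hi = hi, depth = depth)
      if (v < 0L) {
        leaf[-v, ] <<- list(lo, hi, (lo + hi) / 2, depth)
        return(invisible())
      }
      if (hc$height[v] <= 1e-12) {
        # identical (perfectly correlated) clusters: one shared color
        fill_leaves(v, lo, hi, (lo + hi) / 2, depth)
        return(invisible())
      }
      a <- hc$merge[v, 1L]; b <- hc$merge[v, 2L]
      na <- cnt(a); nb <- cnt(b)
      w <- hi - lo
      slot_a <- w * na / (na + nb)
      slot_b <- w - slot_a
      ma <- reserve_fraction * slot_a / 2
      mb <- reserve_fraction * slot_b / 2
      recurse(a, lo + ma, lo + slot_a - ma, depth + 1L)
      recurse(b, lo + slot_a + mb, hi - mb, depth + 1L)
      invisible()
    }
    recurse(nmerge, hue_range[1L], hue_range[2L], 0L)
  }
  ramp <- function(vals, depth) {
    t <- pmin(depth, 4L) / 4
    vals[1L] + (vals[2L] - vals[1L]) * t
  }
  chroma <- ramp(chroma_ramp, leaf$depth)
  lum <- ramp(luminance_ramp, leaf$depth)
  hex <- grDevices::hcl(h = leaf$hue %% 360, c = chroma, l = lum,
                        fixup = TRUE)
  colors <- data.frame(tree$info[, c("cluster_id", "result_id", "label")],
                       h_lo = leaf$h_lo, h_hi = leaf$h_hi, hue = leaf$hue,
                       chroma = chroma, luminance = lum, hex = hex,
                       stringsAsFactors = FALSE)
  structure(list(colors = colors,
                 nodes = if (length(nodes)) do.call(rbind, nodes) else
                   data.frame(node = -1L, h_lo = hue_range[1L],
                              h_hi = hue_range[2L], depth = 0L)),
            class = "color_assignment")
}

#' @export
print.color_assignment <- function(x, ...) {
  cat(sprintf("<color_assignment> %d clusters\n", nrow(x$colors)))
  invisible(x)
}

#' Look up the hex color of one cluster
#' @param colors a `color_assignment`.
#' @param result_id,label cluster coordinates.
#' @return Hex sRGB string.
#' @export
cluster_color <- function(colors, result_id, label) {
  stopifnot(inherits(colors, "color_assignment"))
  i <- which(colors$colors$result_id == result_id &
               colors$colors$label == label)
  if (length(i) != 1L)
    stop("no color for cluster ", result_id, "::", label, call. = FALSE)
  colors$colors$hex[i]
}

#' Serialize a color assignment to JSON
#' @param colors a `color_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colors <- function(colors, path) {
  stopifnot(inherits(colors, "color_assignment"))
  jsonlite::write_json(colors$colors, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
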