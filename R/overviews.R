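## Overview computations (force-directed result map, results dendrogram)
## and static SVG renderers for all views.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_el <- function(name, ..., text = NULL) {
  attrs <- list(...)
  attrs <- attrs[!vapply(attrs, is.null, logical(1L))]
  a <- if (length(attrs))
    paste0(" ", paste(sprintf('%s="%s"', gsub("_", "-", names(attrs)),
                              vapply(attrs, function(v)
                                paste(format(v, trim = TRUE), collapse = " "),
                                character(1L))),
                      collapse = " "))
  else ""
  if (is.null(text)) sprintf("<%s%s/>", name, a)
  else sprintf("<%s%s>%s</%s>", name, a, text, name)
}

svg_doc <- function(width, height, body) {
  paste0(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%g" height="%g" viewBox="0 0 %g %g">'),
    width, height, width, height),
    paste(body, collapse = "\n"), "</svg>")
}

#' Write an SVG document to disk
#' @param svg SVG document string from a renderer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  writeLines(svg, path)
  invisible(path)
}

#' Deterministic spring layout with per-pair rest lengths
#'
#' Gradient descent on the stress Sum (d_ij - L_ij)^2 from seeded random
#' initial positions; used for the result-overview map and the
#' per-result cluster graph.
#' @noRd
spring_layout <- function(L, seed, iterations = 500L) {
  n <- nrow(L)
  set.seed(seed)
  if (n == 1L) return(matrix(0, 1L, 2L))
  p <- matrix(stats::runif(n * 2L, -1, 1), n, 2L)
  for (it in seq_len(iterations)) {
    lr <- 0.1 * (1 - (it - 1L) / iterations) + 0.005
    grad <- matrix(0, n, 2L)
    dx <- outer(p[, 1L], p[, 1L], `-`)
    dy <- outer(p[, 2L], p[, 2L], `-`)
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    coef <- (d - L) / d
    diag(coef) <- 0
    grad[, 1L] <- rowSums(coef * dx)
    grad[, 2L] <- rowSums(coef * dy)
    p <- p - lr * grad / max(1, sqrt(max(rowSums(grad^2))))
  }
  p
}

#' Force-directed overview of clustering results
#'
#' Places one node per result so that more similar results (pair-counting
#' F-measure) sit closer together: spring rest lengths are
#' `0.1 + (1 - F)`, the layout is run to convergence from seeded random
#' positions (deterministic given the seed), and edges are kept for pairs
#' whose similarity exceeds `threshold` (edge filtering happens after
#' layout; the layout itself uses all pairs). Node radius shrinks with
#' the number of results (`0.5 / sqrt(n)`), and when `results` and
#' `colors` are supplied each node carries pie wedges of its cluster
#' sizes in the global cluster colors.
#'
#' @param sm a `similarity_matrix`.
#' @param threshold edge similarity threshold in `[0, 1]` (strict).
#' @param seed integer RNG seed.
#' @param iterations layout iterations.
#' @param results optional list of the underlying `clustering_result`s.
#' @param colors optional `color_assignment` for pie wedges.
#' @return An object of class `fdl_graph`: `positions`, `radius`,
#'   `edges` (data.frame a, b, weight with weight > threshold), `pies`.
#' @export
fdl_overview <- function(sm, threshold = 0.3, seed = 1L,
                         iterations = 500L, results = NULL,
                         colors = NULL) {
  ids <- rownames(sm)
  n <- length(ids)
  L <- 0.1 + (1 - unclass(sm))
  diag(L) <- 0
  p <- spring_layout(L, seed, iterations)
  rownames(p) <- ids
  edges <- data.frame(a = character(), b = character(),
                      weight = numeric())
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
      if (sm[i, j] > threshold)
        edges <- rbind(edges, data.frame(a = ids[i], b = ids[j],
                                         weight = sm[i, j]))
  }
  pies <- NULL
  if (!is.null(results)) {
    names(results) <- vapply(results, `[[`, character(1L), "result_id")
    pies <- lapply(stats::setNames(ids, ids), function(id) {
      r <- results[[id]]
      sizes <- cluster_sizes(r)
      hex <- if (!is.null(colors))
        vapply(names(sizes), function(l) cluster_color(colors, id, l),
               character(1L))
      else rep("#999999", length(sizes))
      data.frame(label = names(sizes), size = as.integer(sizes),
                 hex = hex, stringsAsFactors = FALSE)
    })
  }
  structure(list(positions = p, radius = 0.5 / sqrt(n), edges = edges,
                 threshold = threshold, pies = pies),
            class = "fdl_graph")
}

#' Dendrogram overview of clustering results
#'
#' HAC over results with distance `1 - F`, using the same linkage and
#' deterministic leaf-order conventions as item-level clustering.
#'
#' @param sm a `similarity_matrix` over at least two results.
#' @param linkage linkage method.
#' @return An object of class `results_dendrogram` (an `hclust` plus
#'   labels).
#' @export
results_dendrogram <- function(sm, linkage = "average") {
  ids <- rownames(sm)
  if (length(ids) < 2L)
    stop("need at least 2 results for a dendrogram", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - unclass(sm)), method = linkage)
  hc$labels <- ids
  structure(list(hclust = reorder_hclust(hc), labels = ids),
            class = "results_dendrogram")
}

## ---- renderers -------------------------------------------------------

seg_color <- function(colors, result_id, label, fallback = "#888888") {
  if (is.null(colors)) return(fallback)
  tryCatch(cluster_color(colors, result_id, label),
           error = function(e) fallback)
}

#' Render the enhanced parallel-sets view as SVG
#'
#' Bars are filled with their cluster's global color; each visible stable
#' group runs as a band whose per-gap ribbon is filled with a linear
#' gradient between its two end clusters' colors at reduced opacity.
#' With `common_angle = TRUE` every ribbon is drawn as three runs
#' (vertical, slanted, vertical) sharing one global slant angle, chosen
#' so the widest band's slanted run fits the row gap — the common-angle
#' defense against the line-width illusion. `highlight` (a group index
#' or a `list(result_id=, label=)` cluster) raises the opacity of the
#' matching bands and fades the rest. The stable-group size histogram is
#' drawn beneath the rows.
#'
#' @param layout a `parallel_sets_layout`.
#' @param colors optional `color_assignment` (defaults to the one stored
#'   in the layout).
#' @param common_angle draw bands as common-angle triples?
#' @param highlight optional group index or cluster spec.
#' @return SVG document string.
#' @export
render_parallel_sets <- function(layout, colors = layout$colors,
                                 common_angle = FALSE, highlight = NULL) {
  geom <- layout_geometry(layout)
  G <- length(layout$group_sizes)
  R <- length(layout$row_order)
  bh <- layout$bar_h
  body <- character()
  defs <- character()

  hl_groups <- NULL
  if (!is.null(highlight)) {
    hl_groups <- if (is.list(highlight))
      which(layout$glabel[, highlight$result_id] == highlight$label)
    else as.integer(highlight)
  }
  op_band <- function(g) {
    if (is.null(hl_groups)) 0.6
    else if (g %in% hl_groups) 0.9 else 0.12
  }

  # bars
  for (id in layout$row_order) {
    row <- geom$rows[[id]]
    for (bi in seq_len(nrow(row$bars))) {
      b <- row$bars[bi, ]
      body <- c(body, svg_el("rect", class = "bar",
                             x = b$x0, y = row$y,
                             width = max(b$x1 - b$x0, 0.01), height = bh,
                             fill = seg_color(colors, id, b$label),
                             stroke = "none"))
    }
  }
  # bands
  grad_n <- 0L
  mids <- lapply(layout$row_order,
                 function(id) row_midpoints(geom$rows[[id]], G))
  slope <- NULL
  if (common_angle && R > 1L) {
    maxdx <- 0
    for (ri in seq_len(R - 1L))
      for (g in which(layout$visible))
        maxdx <- max(maxdx, abs(mids[[ri + 1L]][g] - mids[[ri]][g]),
                     na.rm = TRUE)
    slope <- maxdx  # widest band crosses in 80% of the gap (see below)
  }
  for (ri in seq_len(max(R - 1L, 0L))) {
    if (R < 2L) break
    id1 <- layout$row_order[ri]; id2 <- layout$row_order[ri + 1L]
    r1 <- geom$rows[[id1]]; r2 <- geom$rows[[id2]]
    y1 <- r1$y + bh; y2 <- r2$y
    for (g in which(layout$visible)) {
      s1 <- r1$segs[r1$segs$group == g, ]
      s2 <- r2$segs[r2$segs$group == g, ]
      if (nrow(s1) == 0L || nrow(s2) == 0L) next
      c1 <- seg_color(colors, id1, s1$bar)
      c2 <- seg_color(colors, id2, s2$bar)
      grad_n <- grad_n + 1L
      gid <- sprintf("bandgrad%d", grad_n)
      defs <- c(defs, paste0(
        sprintf('<linearGradient id="%s" x1="0" y1="0" x2="0" y2="1">',
                gid),
        sprintf('<stop offset="0" stop-color="%s"/>', c1),
        sprintf('<stop offset="1" stop-color="%s"/>', c2),
        "</linearGradient>"))
      fill <- sprintf("url(#%s)", gid)
      op <- op_band(g)
      if (!common_angle) {
        body <- c(body, svg_el(
          "polygon", class = "band", data_group = g,
          points = sprintf("%g,%g %g,%g %g,%g %g,%g",
                           s1$x0, y1, s1$x1, y1, s2$x1, y2, s2$x0, y2),
          fill = fill, fill_opacity = op))
      } else {
        hgap <- y2 - y1
        dx <- s2$mid - s1$mid
        dyn <- if (slope > 0) abs(dx) / slope * 0.8 * hgap else 0
        ya <- y1 + (hgap - dyn) / 2
        yb <- ya + dyn
        w1 <- s1$x1 - s1$x0; w2 <- s2$x1 - s2$x0
        quad <- function(xa0, xa1, ya_, xb0, xb1, yb_)
          svg_el("polygon", class = "band", data_group = g,
                 points = sprintf("%g,%g %g,%g %g,%g %g,%g",
                                  xa0, ya_, xa1, ya_, xb1, yb_, xb0, yb_),
                 fill = fill, fill_opacity = op)
        body <- c(body,
                  quad(s1$x0, s1$x1, y1, s1$x0, s1$x1, ya),
                  quad(s1$x0, s1$x1, ya,
                       s1$x0 + dx + (w1 - w2) * 0,
                       s1$x0 + dx + w1, yb),
                  quad(s2$x0, s2$x1, yb, s2$x0, s2$x1, y2))
      }
    }
  }
  # per-row segment outlines for visible groups
  for (id in layout$row_order) {
    row <- geom$rows[[id]]
    vs <- row$segs[row$segs$visible, , drop = FALSE]
    for (si in seq_len(nrow(vs)))
      body <- c(body, svg_el("rect", class = "band-seg",
                             data_group = vs$group[si],
                             x = vs$x0[si], y = row$y,
                             width = max(vs$x1[si] - vs$x0[si], 0.01),
                             height = bh, fill = "none",
                             stroke = "#333333", stroke_opacity = 0.25))
  }
  # stable-group histogram with filter bounds
  hist_y <- geom$height + 30
  hist_h <- 60
  tab <- group_histogram(structure(
    list(groups = split(seq_len(sum(layout$group_sizes)),
                        rep(seq_len(G), layout$group_sizes)),
         visible = layout$visible), class = "stable_group_set"))
  sizes <- as.integer(names(tab))
  maxc <- max(tab)
  bw <- layout$W / max(length(tab), 1L)
  vis_sizes <- layout$group_sizes[layout$visible]
  for (i in seq_along(tab)) {
    h <- tab[i] / maxc * hist_h
    inside <- length(vis_sizes) > 0 && sizes[i] >= min(vis_sizes) &&
      sizes[i] <= max(vis_sizes)
    body <- c(body, svg_el("rect", class = "hist",
                           x = (i - 1) * bw + 1, y = hist_y + hist_h - h,
                           width = bw - 2, height = h,
                           fill = if (inside) "#4477aa" else "#bbbbbb"),
              svg_el("text", x = (i - 0.5) * bw,
                     y = hist_y + hist_h + 12, font_size = 9,
                     text_anchor = "middle",
                     text = xml_escape(as.character(sizes[i]))))
  }
  height <- hist_y + hist_h + 20
  svg_doc(layout$W, height,
          c("<defs>", defs, "</defs>", body))
}

#' Render the force-directed results overview
#'
#' Nodes are pie charts of cluster sizes (when present), edges connect
#' supra-threshold pairs with stroke width proportional to similarity.
#'
#' @param g an `fdl_graph`.
#' @param size canvas size in user units.
#' @return SVG document string.
#' @export
render_fdl <- function(g, size = 400) {
  stopifnot(inherits(g, "fdl_graph"))
  p <- g$positions
  rng <- apply(p, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-9)
  pad <- 60
  sc <- function(xy) {
    cbind((xy[, 1L] - rng[1L, 1L]) / span[1L] * (size - 2 * pad) + pad,
          (xy[, 2L] - rng[1L, 2L]) / span[2L] * (size - 2 * pad) + pad)
  }
  q <- sc(p)
  rownames(q) <- rownames(p)
  body <- character()
  if (nrow(g$edges) > 0L) for (e in seq_len(nrow(g$edges))) {
    a <- q[g$edges$a[e], ]; b <- q[g$edges$b[e], ]
    body <- c(body, svg_el("line", class = "edge",
                           x1 = a[1L], y1 = a[2L], x2 = b[1L], y2 = b[2L],
                           stroke = "#777777",
                           stroke_width = 0.5 + 4 * g$edges$weight[e]))
  }
  rad <- g$radius * (size - 2 * pad) / 4
  for (id in rownames(q)) {
    cx <- q[id, 1L]; cy <- q[id, 2L]
    pie <- if (!is.null(g$pies)) g$pies[[id]]
    if (is.null(pie) || nrow(pie) == 1L) {
      fill <- if (!is.null(pie)) pie$hex[1L] else "#4477aa"
      body <- c(body, svg_el("circle", class = "node", cx = cx, cy = cy,
                             r = rad, fill = fill, stroke = "#333333"))
    } else {
      ang <- 2 * pi * cumsum(c(0, pie$size / sum(pie$size)))
      for (w in seq_len(nrow(pie))) {
        a0 <- ang[w] - pi / 2; a1 <- ang[w + 1L] - pi / 2
        large <- as.integer((a1 - a0) > pi)
        body <- c(body, svg_el("path", class = "wedge",
          d = sprintf("M %g %g L %g %g A %g %g 0 %d 1 %g %g Z",
                      cx, cy,
                      cx + rad * cos(a0), cy + rad * sin(a0),
                      rad, rad, large,
                      cx + rad * cos(a1), cy + rad * sin(a1)),
          fill = pie$hex[w], stroke = "#ffffff", stroke_width = 0.5))
      }
    }
    body <- c(body, svg_el("text", x = cx, y = cy - rad - 4,
                           font_size = 10, text_anchor = "middle",
                           text = xml_escape(id)))
  }
  svg_doc(size, size, body)
}

#' Dendrogram drawing segments from an hclust tree
#' @noRd
dendro_segments <- function(hc, leaf_x, yscale) {
  nmerge <- nrow(hc$merge)
  nodex <- numeric(nmerge); nodey <- numeric(nmerge)
  segs <- list()
  getx <- function(v) if (v < 0L) leaf_x[match(-v, hc$order)] else nodex[v]
  gety <- function(v) if (v < 0L) 0 else nodey[v]
  for (i in seq_len(nmerge)) {
    a <- hc$merge[i, 1L]; b <- hc$merge[i, 2L]
    xa <- getx(a); xb <- getx(b)
    ya <- gety(a); yb <- gety(b)
    h <- hc$height[i] * yscale
    nodex[i] <- (xa + xb) / 2; nodey[i] <- h
    segs[[i]] <- data.frame(x0 = c(xa, xb, xa), y0 = c(ya, yb, h),
                            x1 = c(xa, xb, xb), y1 = c(h, h, h))
  }
  do.call(rbind, segs)
}

#' Render the results-dendrogram overview
#'
#' Dendrogram over results (distance `1 - F`) with, under each leaf, a
#' miniature strip of that result's cluster sizes in their global colors.
#'
#' @param d a `results_dendrogram`.
#' @param results optional list of `clustering_result`s for the strips.
#' @param colors optional `color_assignment`.
#' @param width,height canvas size.
#' @return SVG document string.
#' @export
render_results_dendrogram <- function(d, results = NULL, colors = NULL,
                                      width = 500, height = 300) {
  stopifnot(inherits(d, "results_dendrogram"))
  hc <- d$hclust
  n <- length(hc$labels)
  leaf_x <- seq(0.5, n - 0.5) / n * (width - 40) + 20
  tree_h <- height - 90
  yscale <- tree_h / max(hc$height, 1e-9)
  segs <- dendro_segments(hc, leaf_x, yscale)
  body <- vapply(seq_len(nrow(segs)), function(i)
    svg_el("line", class = "tree", x1 = segs$x0[i],
           y1 = tree_h - segs$y0[i] + 10,
           x2 = segs$x1[i], y2 = tree_h - segs$y1[i] + 10,
           stroke = "#333333"), character(1L))
  strip_y <- tree_h + 20
  leaves <- hc$labels[hc$order]
  if (!is.null(results))
    names(results) <- vapply(results, `[[`, character(1L), "result_id")
  for (i in seq_along(leaves)) {
    id <- leaves[i]
    x0 <- leaf_x[i] - (width - 40) / n / 2 + 2
    wtot <- (width - 40) / n - 4
    if (!is.null(results) && !is.null(results[[id]])) {
      sizes <- cluster_sizes(results[[id]])
      frac <- sizes / sum(sizes)
      x <- x0
      for (li in seq_along(sizes)) {
        body <- c(body, svg_el("rect", class = "strip",
                               x = x, y = strip_y,
                               width = max(frac[li] * wtot, 0.01),
                               height = 12,
                               fill = seg_color(colors, id,
                                                names(sizes)[li])))
        x <- x + frac[li] * wtot
      }
    }
    body <- c(body, svg_el("text", x = leaf_x[i], y = strip_y + 26,
                           font_size = 8, text_anchor = "middle",
                           text = xml_escape(id)))
  }
  svg_doc(width, height, body)
}

#' Render the parameter-information view
#'
#' One subsection per algorithm; within it one bar per canonical
#' parameter setting, bar height proportional to how many registered
#' results used that setting.
#'
#' @param counts the data.frame from [parameter_counts()].
#' @param width canvas width.
#' @return SVG document string.
#' @export
render_parameter_counts <- function(counts, width = 500) {
  algs <- unique(counts$algorithm)
  row_h <- 90
  body <- character()
  for (ai in seq_along(algs)) {
    sub <- counts[counts$algorithm == algs[ai], , drop = FALSE]
    y0 <- (ai - 1L) * row_h
    body <- c(body, svg_el("text", x = 4, y = y0 + 12, font_size = 11,
                           text = xml_escape(algs[ai])))
    maxc <- max(sub$count)
    bw <- (width - 20) / nrow(sub)
    for (i in seq_len(nrow(sub))) {
      h <- sub$count[i] / maxc * (row_h - 40)
      body <- c(body,
                svg_el("rect", class = "count-bar",
                       x = 10 + (i - 1) * bw, y = y0 + row_h - 24 - h,
                       width = bw - 4, height = h, fill = "#4477aa",
                       data_count = sub$count[i]),
                svg_el("text", x = 10 + (i - 0.5) * bw,
                       y = y0 + row_h - 10, font_size = 8,
                       text_anchor = "middle",
                       text = xml_escape(sub$setting[i])))
    }
  }
  svg_doc(width, row_h * length(algs), body)
}

#' Render an OPTICS reachability plot with cluster bars and profiles
#'
#' Bar chart of reachability distances in processing order (infinite
#' values drawn at 1.1 times the maximum finite reachability), one
#' colored horizontal interval per extracted non-noise cluster under the
#' plot spanning its start..end ordering positions, and a
#' parallel-coordinates panel of member profiles beneath, colored by
#' cluster.
#'
#' @param o an `optics_result`.
#' @param cr the [extract_optics_clusters()] result derived from `o`.
#' @param colors optional `color_assignment`.
#' @param m the `expr_matrix`.
#' @param width canvas width.
#' @return SVG document string.
#' @export
render_reachability <- function(o, cr, colors = NULL, m, width = 600) {
  stopifnot(inherits(o, "optics_result"),
            inherits(cr, "clustering_result"))
  if (!setequal(o$ordering, names(cr$assignment)))
    stop("clustering result does not match the OPTICS ordering",
         call. = FALSE)
  n <- length(o$ordering)
  plot_h <- 120; bars_y <- plot_h + 8; pc_y <- bars_y + 24
  pc_h <- 100
  finite <- o$reachability[is.finite(o$reachability)]
  cap <- if (length(finite)) 1.1 * max(finite) else 1
  if (cap == 0) cap <- 1
  bw <- width / n
  body <- character()
  for (i in seq_len(n)) {
    r <- o$reachability[i]
    h <- min(r, cap) / cap * plot_h
    body <- c(body, svg_el("rect", class = "reach",
                           x = (i - 1) * bw, y = plot_h - h,
                           width = max(bw - 0.5, 0.2), height = h,
                           fill = if (is.finite(r)) "#555555"
                                  else "#aa3333"))
  }
  spans <- cr$extra$spans
  if (length(spans)) for (lab in names(spans)) {
    sp <- spans[[lab]]
    body <- c(body, svg_el("rect", class = "cluster-bar",
                           x = (sp[["start"]] - 1) * bw, y = bars_y,
                           width = (sp[["end"]] - sp[["start"]] + 1) * bw,
                           height = 10,
                           fill = seg_color(colors, cr$result_id, lab)))
  }
  rngv <- range(m$values)
  ncond <- ncol(m$values)
  px <- seq(0, width - 10, length.out = ncond) + 5
  for (it in o$ordering) {
    v <- m$values[it, ]
    yy <- pc_y + pc_h - (v - rngv[1L]) / max(diff(rngv), 1e-9) * pc_h
    lab <- cr$assignment[[it]]
    col <- if (identical(lab, cr$noise_label)) "#cccccc"
           else seg_color(colors, cr$result_id, lab)
    body <- c(body, svg_el("polyline", class = "profile",
                           points = paste(sprintf("%g,%g", px, yy),
                                          collapse = " "),
                           fill = "none", stroke = col,
                           stroke_opacity = 0.5))
  }
  svg_doc(width, pc_y + pc_h + 10, body)
}

#' Render a self-organizing map grid
#'
#' Hexagonal cells with background intensity proportional to cluster
#' size and a line glyph of the cell's mean member profile.
#'
#' @param s a `som_result`.
#' @param m the `expr_matrix`.
#' @param colors optional `color_assignment` (cell border colors).
#' @param cell_r hexagon radius in user units.
#' @return SVG document string.
#' @export
render_som <- function(s, m, colors = NULL, cell_r = 40) {
  stopifnot(inherits(s, "som_result"))
  sizes <- integer(length(s$cell_labels))
  tab <- table(s$cell_of)
  sizes[as.integer(names(tab))] <- as.integer(tab)
  maxs <- max(sizes, 1L)
  hexpts <- function(cx, cy, r) {
    a <- pi / 6 + seq(0, 5) * pi / 3
    paste(sprintf("%g,%g", cx + r * cos(a), cy + r * sin(a)),
          collapse = " ")
  }
  sc <- 2 * cell_r * 0.95
  body <- character()
  for (ci in seq_along(s$cell_labels)) {
    cx <- s$cell_x[ci] * sc; cy <- s$cell_y[ci] * sc + cell_r
    intensity <- sizes[ci] / maxs
    gray <- grDevices::gray(1 - 0.75 * intensity)
    border <- seg_color(colors, s$clustering$result_id,
                        s$cell_labels[ci], fallback = "#444444")
    body <- c(body, svg_el("polygon", class = "cell",
                           points = hexpts(cx, cy, cell_r),
                           fill = gray, stroke = border,
                           stroke_width = 2,
                           data_size = sizes[ci]))
    if (sizes[ci] > 0L) {
      members <- names(s$cell_of)[s$cell_of == ci]
      prof <- colMeans(m$values[members, , drop = FALSE])
      rngv <- range(m$values)
      px <- seq(cx - cell_r * 0.6, cx + cell_r * 0.6,
                length.out = length(prof))
      py <- cy + cell_r * 0.5 -
        (prof - rngv[1L]) / max(diff(rngv), 1e-9) * cell_r
      body <- c(body, svg_el("polyline", class = "glyph",
                             points = paste(sprintf("%g,%g", px, py),
                                            collapse = " "),
                             fill = "none", stroke = "#222222"))
    }
  }
  w <- (max(s$cell_x) + 1) * sc + cell_r
  h <- max(s$cell_y) * sc + 3 * cell_r
  svg_doc(w, h, body)
}

#' Render a per-result cluster graph
#'
#' Force-directed layout of one result's clusters: rectangle area
#' proportional to cluster size, mean-profile line glyph inside, edges
#' weighted by centroid correlation (drawn when positive).
#'
#' @param r a `clustering_result`.
#' @param m the `expr_matrix`.
#' @param colors optional `color_assignment`.
#' @param seed layout seed.
#' @param size canvas size.
#' @return SVG document string.
#' @export
render_cluster_graph <- function(r, m, colors = NULL, seed = 1L,
                                 size = 400) {
  stopifnot(inherits(r, "clustering_result"))
  labs <- names(r$clusters)
  k <- length(labs)
  cents <- t(vapply(labs, function(l) cluster_centroid(r, l, m),
                    numeric(ncol(m$values))))
  cors <- if (k >= 2L && ncol(m$values) >= 2L) {
    cc <- suppressWarnings(stats::cor(t(cents)))
    cc[is.na(cc)] <- 0; cc
  } else diag(1, k)
  L <- 0.1 + (1 - cors) / 2
  diag(L) <- 0
  p <- spring_layout(L, seed)
  rng <- apply(p, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-9)
  pad <- 70
  q <- cbind((p[, 1L] - rng[1L, 1L]) / span[1L] * (size - 2 * pad) + pad,
             (p[, 2L] - rng[1L, 2L]) / span[2L] * (size - 2 * pad) + pad)
  sizes <- cluster_sizes(r)
  area <- sizes / max(sizes) * 2200
  side <- sqrt(area)
  body <- character()
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
    if (cors[i, j] > 0)
      body <- c(body, svg_el("line", class = "edge",
                             x1 = q[i, 1L], y1 = q[i, 2L],
                             x2 = q[j, 1L], y2 = q[j, 2L],
                             stroke = "#999999",
                             stroke_width = 0.5 + 3 * cors[i, j]))
  rngv <- range(m$values)
  for (i in seq_len(k)) {
    w <- side[i]
    body <- c(body, svg_el("rect", class = "cluster-node",
                           x = q[i, 1L] - w / 2, y = q[i, 2L] - w / 2,
                           width = w, height = w,
                           fill = seg_color(colors, r$result_id, labs[i]),
                           fill_opacity = 0.85, stroke = "#333333",
                           data_size = sizes[i]))
    px <- seq(q[i, 1L] - w / 2 + 2, q[i, 1L] + w / 2 - 2,
              length.out = ncol(m$values))
    py <- q[i, 2L] + w / 2 - 2 -
      (cents[i, ] - rngv[1L]) / max(diff(rngv), 1e-9) * (w - 4)
    body <- c(body, svg_el("polyline", class = "glyph",
                           points = paste(sprintf("%g,%g", px, py),
                                          collapse = " "),
                           fill = "none", stroke = "#111111"))
  }
  svg_doc(size, size, body)
}

#' Render a dendrogram-plus-heatmap view of an item hierarchy
#'
#' Item dendrogram on top, heatmap of the matrix in dendrogram leaf
#' order below, a similarity-bar marker at the cut threshold, and a
#' miniature whole-matrix heatmap overview in the corner.
#'
#' @param h an `hclust_result` from [hac_items()].
#' @param m the `expr_matrix`.
#' @param cut similarity threshold drawn as the minimum similarity bar.
#' @param width canvas width.
#' @return SVG document string.
#' @export
render_dendro_heatmap <- function(h, m, cut = NULL, width = 600) {
  stopifnot(inherits(h, "hclust_result"), inherits(m, "expr_matrix"))
  hc <- h$hclust
  n <- length(h$labels)
  tree_h <- 120
  leaf_x <- seq(0.5, n - 0.5) / n * (width - 80) + 70
  yscale <- tree_h / max(hc$height, 1e-9)
  segs <- dendro_segments(hc, leaf_x, yscale)
  body <- vapply(seq_len(nrow(segs)), function(i)
    svg_el("line", class = "tree", x1 = segs$x0[i],
           y1 = tree_h - segs$y0[i] + 5,
           x2 = segs$x1[i], y2 = tree_h - segs$y1[i] + 5,
           stroke = "#333333"), character(1L))
  if (!is.null(cut)) {
    hmax <- max(hc$height)
    hcut <- if (h$metric == "correlation") 1 - cut
            else (1 - cut) * (if (hmax > 0) hmax else 1)
    ycut <- tree_h - hcut * yscale + 5
    body <- c(body, svg_el("line", class = "similarity-bar",
                           x1 = 60, y1 = ycut, x2 = width - 5, y2 = ycut,
                           stroke = "#cc0000", stroke_dasharray = "4 3"))
  }
  # heatmap in leaf order
  vals <- m$values[h$labels[hc$order], , drop = FALSE]
  rngv <- range(vals)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(64)
  idx <- function(v) pmin(64L, pmax(1L, 1L +
    as.integer((v - rngv[1L]) / max(diff(rngv), 1e-9) * 63)))
  hm_y <- tree_h + 15
  ch <- max(1, min(8, 260 / ncol(vals)))
  cw <- (width - 80) / n
  for (j in seq_len(ncol(vals))) {
    cols <- pal[idx(vals[, j])]
    for (i in seq_len(n))
      body <- c(body, svg_el("rect", class = "hm",
                             x = 70 + (i - 1) * cw,
                             y = hm_y + (j - 1) * ch,
                             width = cw, height = ch, fill = cols[i]))
  }
  # miniature whole-matrix overview, original row order
  mini_w <- 40; mini_h <- ncol(m$values) * 3
  mw <- mini_w / nrow(m$values); mh <- 3
  for (j in seq_len(ncol(m$values))) {
    cols <- pal[idx(m$values[, j])]
    for (i in seq_len(nrow(m$values)))
      body <- c(body, svg_el("rect", class = "mini",
                             x = 10 + (i - 1) * mw,
                             y = hm_y + (j - 1) * mh,
                             width = max(mw, 0.2), height = mh,
                             fill = cols[i]))
  }
  svg_doc(width, hm_y + max(ncol(vals) * ch, mini_h) + 10, body)
}
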