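#' Order clustering results for the parallel-sets view
#'
#' Seriation of results so similar ones sit in adjacent rows.
#' `method = "leaf_order"` takes the leaf sequence of the results
#' dendrogram (HAC on `1 - F`). `method = "greedy_chain"` starts from the
#' most similar pair and repeatedly appends, at either end of the chain,
#' the unplaced result most similar to that end; ties are broken by
#' lexicographic result ID.
#'
#' @param sm a `similarity_matrix`.
#' @param method `"greedy_chain"` or `"leaf_order"`.
#' @return Character vector of result IDs, top row first.
#' @export
order_results <- function(sm, method = c("greedy_chain", "leaf_order")) {
  method <- match.arg(method)
  ids <- rownames(sm)
  n <- length(ids)
  if (n == 1L) return(ids)
  if (method == "leaf_order") {
    d <- stats::as.dist(1 - sm)
    hc <- reorder_hclust(stats::hclust(d, method = "average"))
    return(ids[hc$order])
  }
  s <- unclass(sm)
  # most similar pair, ties toward lexicographically smaller ids
  best <- c(NA_integer_, NA_integer_); bestv <- -Inf
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- s[i, j]
    cand <- sort(c(ids[i], ids[j]))
    if (v > bestv ||
        (v == bestv && paste(cand, collapse = "\r") <
           paste(sort(ids[best]), collapse = "\r"))) {
      best <- c(i, j); bestv <- v
    }
  }
  chain <- ids[best][order(ids[best])]
  rest <- setdiff(ids, chain)
  while (length(rest)) {
    headv <- s[chain[1L], rest]
    tailv <- s[chain[length(chain)], rest]
    pick_end <- function(v) {
      top <- rest[v == max(v)]
      sort(top)[1L]
    }
    hbest <- pick_end(headv); tbest <- pick_end(tailv)
    if (max(tailv) >= max(headv)) {
      chain <- c(chain, tbest); rest <- setdiff(rest, tbest)
    } else {
      chain <- c(hbest, chain); rest <- setdiff(rest, hbest)
    }
  }
  chain
}

#' Build a parallel-sets layout
#'
#' Each clustering result is one horizontal row of stacked bars (its
#' clusters, width proportional to cluster size, separated by a small
#' gap); each visible stable group is a band running through one segment
#' per row, width proportional to group size. Hidden (size-filtered)
#' groups keep proportional blank space inside their bars so bar widths
#' stay comparable. Vertical spacing between adjacent rows is
#' proportional to their dissimilarity `1 - F`, floored at 15% of the
#' largest spacing so identical results remain separated.
#'
#' @param results list of `clustering_result`s sharing one item set.
#' @param sgs a `stable_group_set` over (at least) those results.
#' @param colors optional `color_assignment` carried for rendering.
#' @param row_order optional explicit top-to-bottom order of result IDs;
#'   defaults to the order of `results`.
#' @param bar_order optional named list (per result ID) of manual bar
#'   label orders; such rows are frozen under [rearrange_bars()].
#' @param W total layout width in user units (> 0).
#' @param gap horizontal gap between adjacent bars.
#' @return An object of class `parallel_sets_layout`.
#' @export
build_layout <- function(results, sgs, colors = NULL, row_order = NULL,
                         bar_order = NULL, W = 1000, gap = 4) {
  stopifnot(inherits(sgs, "stable_group_set"), length(results) >= 1L)
  if (W <= 0) stop("zero-width layout", call. = FALSE)
  ids <- vapply(results, `[[`, character(1L), "result_id")
  names(results) <- ids
  if (is.null(row_order)) row_order <- ids
  stopifnot(all(row_order %in% ids), !anyDuplicated(row_order))
  # groups must be signatures over (a superset of) the displayed results
  G <- length(sgs$groups)
  glabel <- matrix(NA_character_, G, length(ids), dimnames = list(NULL, ids))
  for (g in seq_len(G)) {
    rep_item <- sgs$groups[[g]][1L]
    for (id in ids) {
      lab <- results[[id]]$assignment[[rep_item]]
      if (is.null(lab))
        stop("result ", id, " does not cover item ", rep_item,
             call. = FALSE)
      glabel[g, id] <- lab
    }
  }
  frozen <- character()
  bars <- list(); segs <- list()
  for (id in ids) {
    sizes <- cluster_sizes(results[[id]])
    ord <- names(sizes)[order(-sizes, names(sizes))]  # descending size
    if (!is.null(bar_order) && !is.null(bar_order[[id]])) {
      stopifnot(setequal(bar_order[[id]], ord))
      ord <- bar_order[[id]]
      frozen <- c(frozen, id)
    }
    bars[[id]] <- ord
    segs[[id]] <- lapply(stats::setNames(ord, ord), function(lab)
      which(glabel[, id] == lab))
    # groups must refine every displayed result's clusters
    bw <- vapply(segs[[id]], function(gi) sum(lengths(sgs$groups)[gi]),
                 numeric(1L))
    if (!isTRUE(all.equal(unname(bw[names(sizes)]), unname(as.numeric(sizes)))))
      stop("stable groups do not refine result ", id,
           "; build them over the displayed results", call. = FALSE)
  }
  # adjacent-row dissimilarity for vertical spacing
  dis <- if (length(row_order) > 1L)
    vapply(seq_len(length(row_order) - 1L), function(i)
      1 - f_measure(results[[row_order[i]]], results[[row_order[i + 1L]]],
                    restrict = TRUE),
      numeric(1L))
  else numeric()
  layout <- structure(list(
    group_sizes = lengths(sgs$groups),
    signatures = sgs$signatures,
    visible = sgs$visible,
    glabel = glabel,
    row_order = row_order,
    bar_order = bars,
    seg_order = segs,
    frozen = frozen,
    row_dissim = dis,
    colors = colors,
    W = W, gap = gap, bar_h = 18, row_unit = 120, min_vgap = 30),
    class = "parallel_sets_layout")
  layout
}

#' @export
print.parallel_sets_layout <- function(x, ...) {
  cat(sprintf(
    "<parallel_sets_layout> %d rows, %d groups (%d visible), W=%g\n",
    length(x$row_order), length(x$group_sizes), sum(x$visible), x$W))
  invisible(x)
}

#' Concrete geometry of a parallel-sets layout
#'
#' Resolves the stored orders into coordinates: per row its vertical
#' position and bar extents, per bar its ordered segments with horizontal
#' extents and midpoints. Hidden groups receive coordinates (their blank
#' slot) but are marked invisible.
#'
#' @param layout a `parallel_sets_layout`.
#' @return List with `rows` (named list per result ID: `y`, `bars`
#'   data.frame, `segs` data.frame) and `height`.
#' @export
layout_geometry <- function(layout) {
  n_items <- sum(layout$group_sizes)
  maxd <- if (length(layout$row_dissim)) max(layout$row_dissim) else 0
  y <- 0
  rows <- list()
  for (ri in seq_along(layout$row_order)) {
    id <- layout$row_order[ri]
    ord <- layout$bar_order[[id]]
    nb <- length(ord)
    scale <- (layout$W - layout$gap * (nb - 1L)) / n_items
    x <- 0
    bar_rows <- list(); seg_rows <- list()
    for (lab in ord) {
      gidx <- layout$seg_order[[id]][[lab]]
      bw <- sum(layout$group_sizes[gidx]) * scale
      bar_rows[[lab]] <- data.frame(label = lab, x0 = x, x1 = x + bw,
                                    stringsAsFactors = FALSE)
      sx <- x
      for (g in gidx) {
        w <- layout$group_sizes[g] * scale
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(group = g, bar = lab, x0 = sx, x1 = sx + w,
                     mid = sx + w / 2, visible = layout$visible[g],
                     stringsAsFactors = FALSE)
        sx <- sx + w
      }
      x <- x + bw + layout$gap
    }
    rows[[id]] <- list(
      y = y,
      bars = do.call(rbind, c(bar_rows, list(make.row.names = FALSE))),
      segs = if (length(seg_rows))
        do.call(rbind, c(seg_rows, list(make.row.names = FALSE)))
      else data.frame(group = integer(), bar = character(),
                      x0 = numeric(), x1 = numeric(), mid = numeric(),
                      visible = logical()))
    if (ri < length(layout$row_order)) {
      d <- layout$row_dissim[ri]
      eff <- if (maxd > 0) max(d, 0.15 * maxd) else 0
      y <- y + layout$bar_h + layout$min_vgap + eff * layout$row_unit
    }
  }
  list(rows = rows, height = y + layout$bar_h)
}

#' Midpoints of every group's segment in one row
#' @noRd
row_midpoints <- function(geom_row, n_groups) {
  m <- rep(NA_real_, n_groups)
  m[geom_row$segs$group] <- geom_row$segs$mid
  m
}

#' Fast per-group segment midpoints of one row, straight from the stored
#' orders (no geometry frames); used by the crossing counter and the
#' barycenter sweeps.
#' @noRd
fast_midpoints <- function(layout, id) {
  n_items <- sum(layout$group_sizes)
  ord <- layout$bar_order[[id]]
  scale <- (layout$W - layout$gap * (length(ord) - 1L)) / n_items
  mids <- rep(NA_real_, length(layout$group_sizes))
  x <- 0
  for (lab in ord) {
    gidx <- layout$seg_order[[id]][[lab]]
    if (length(gidx)) {
      w <- layout$group_sizes[gidx] * scale
      ends <- x + cumsum(w)
      mids[gidx] <- ends - w / 2
      x <- ends[length(ends)]
    }
    x <- x + layout$gap
  }
  mids
}

#' Count band crossings of a layout
#'
#' For each pair of adjacent rows, counts the unordered pairs of visible
#' bands whose segment-midpoint order differs between the two rows;
#' returns the sum over all adjacent row pairs.
#'
#' @param layout a `parallel_sets_layout`.
#' @return Non-negative integer.
#' @export
count_crossings <- function(layout) {
  vis <- which(layout$visible)
  if (length(vis) < 2L || length(layout$row_order) < 2L) return(0L)
  mids <- lapply(layout$row_order, function(id)
    fast_midpoints(layout, id)[vis])
  total <- 0L
  for (ri in seq_len(length(layout$row_order) - 1L)) {
    # inversions between the two midpoint orders
    o1 <- order(mids[[ri]])
    r2 <- mids[[ri + 1L]][o1]
    for (i in seq_len(length(r2) - 1L))
      total <- total + sum(r2[seq(i + 1L, length(r2))] < r2[i])
  }
  as.integer(total)
}

#' All permutations of a vector (deterministic order)
#' @noRd
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Size of the joint (bar order x within-bar order) search space
#' @noRd
enum_budget <- function(layout) {
  prod(vapply(layout$row_order, function(id) {
    segs <- layout$seg_order[[id]]
    b <- if (id %in% layout$frozen) 1 else factorial(length(segs))
    b * prod(factorial(lengths(segs)))
  }, numeric(1L)))
}

#' Exhaustive search over bar and segment orders; returns the first
#' minimum-crossing configuration in deterministic enumeration order.
#' Frozen rows keep their bar order.
#' @noRd
exact_min_layout <- function(layout) {
  per_row <- lapply(layout$row_order, function(id) {
    bar_perms <- if (id %in% layout$frozen) list(layout$bar_order[[id]])
                 else all_perms(layout$bar_order[[id]])
    combos <- list()
    for (bp in bar_perms) {
      segls <- lapply(bp, function(lab)
        all_perms(layout$seg_order[[id]][[lab]]))
      grid <- lapply(segls[[1L]], list)
      if (length(bp) > 1L) for (bi in seq(2L, length(bp)))
        grid <- unlist(lapply(grid, function(g)
          lapply(segls[[bi]], function(sp) c(g, list(sp)))),
          recursive = FALSE)
      for (g in grid)
        combos[[length(combos) + 1L]] <-
          list(bars = bp, segs = stats::setNames(g, bp))
    }
    combos
  })
  best <- NULL; best_cc <- Inf
  idx <- rep(1L, length(per_row))
  repeat {
    trial <- layout
    for (ri in seq_along(per_row)) {
      cmb <- per_row[[ri]][[idx[ri]]]
      trial$bar_order[[layout$row_order[ri]]] <- cmb$bars
      trial$seg_order[[layout$row_order[ri]]] <- cmb$segs
    }
    cc <- count_crossings(trial)
    if (cc < best_cc) { best <- trial; best_cc <- cc }
    if (best_cc == 0L) break
    ri <- 1L
    while (ri <= length(per_row)) {
      idx[ri] <- idx[ri] + 1L
      if (idx[ri] <= length(per_row[[ri]])) break
      idx[ri] <- 1L; ri <- ri + 1L
    }
    if (ri > length(per_row)) break
  }
  best
}

#' Barycenter rearrangement of bars (clusters) within rows
#'
#' Sugiyama-style sweeps: top-to-bottom then bottom-to-top, each row's
#' bars re-sorted by the mean horizontal midpoint of their stable groups'
#' segments in the adjacent already-ordered row; ties keep the current
#' relative order, and a greedy adjacent-transposition pass polishes the
#' result. When the joint search space of bar and band orders is small
#' enough (`exact_limit` configurations) the bar orders are instead
#' taken from an exhaustive minimum-crossing search, so tiny instances
#' are arranged optimally. Rows whose bar order was supplied manually at
#' build time are frozen. Membership, sizes and row order are untouched
#' — only bar orders (geometry) change, and the result never has more
#' crossings than the input.
#'
#' @param layout a `parallel_sets_layout`.
#' @param sweeps number of down-and-up sweep pairs.
#' @param exact_limit exhaustive-search budget for small instances.
#' @return The layout with updated bar orders.
#' @export
rearrange_bars <- function(layout, sweeps = 2L, exact_limit = 5000) {
  stopifnot(inherits(layout, "parallel_sets_layout"))
  R <- length(layout$row_order)
  if (R < 2L) return(layout)
  if (enum_budget(layout) <= exact_limit) {
    best <- exact_min_layout(layout)
    layout$bar_order <- best$bar_order
    return(layout)
  }
  entry <- layout
  entry_cc <- count_crossings(layout)
  G <- length(layout$group_sizes)
  resort_row <- function(layout, id, ref_id) {
    if (id %in% layout$frozen) return(layout)
    refmid <- fast_midpoints(layout, ref_id)
    own <- fast_midpoints(layout, id)
    ord <- layout$bar_order[[id]]
    key <- vapply(ord, function(lab) {
      gidx <- layout$seg_order[[id]][[lab]]
      mids <- refmid[gidx]
      if (all(is.na(mids))) mean(own[gidx]) else mean(mids, na.rm = TRUE)
    }, numeric(1L))
    layout$bar_order[[id]] <- ord[order(key)]
    layout
  }
  for (s in seq_len(sweeps)) {
    for (ri in seq(2L, R))
      layout <- resort_row(layout, layout$row_order[ri],
                           layout$row_order[ri - 1L])
    for (ri in seq(R - 1L, 1L))
      layout <- resort_row(layout, layout$row_order[ri],
                           layout$row_order[ri + 1L])
  }
  # greedy adjacent-transposition polish: swap neighboring bars while the
  # total crossing count strictly decreases
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 200L) {
    improved <- FALSE; guard <- guard + 1L
    base <- count_crossings(layout)
    for (id in setdiff(layout$row_order, layout$frozen)) {
      ord <- layout$bar_order[[id]]
      if (length(ord) < 2L) next
      for (i in seq_len(length(ord) - 1L)) {
        trial <- layout
        trial$bar_order[[id]][c(i, i + 1L)] <-
          trial$bar_order[[id]][c(i + 1L, i)]
        cc <- count_crossings(trial)
        if (cc < base) {
          layout <- trial; base <- cc; improved <- TRUE
        }
      }
    }
  }
  if (count_crossings(layout) > entry_cc) return(entry)
  layout
}

#' Rearrangement of band segments within bars
#'
#' With bar orders fixed, sorts the segments inside each bar by the
#' horizontal midpoint of the same group's segment in the previous row
#' (first row: in the next row), breaking ties by group signature. When
#' the within-bar order space is small enough (`exact_limit`
#' configurations) the segment orders are taken from an exhaustive
#' minimum-crossing search instead. On moderately small instances (at
#' most `polish_limit` groups) the sweeps are augmented with a
#' local-search polish that greedily applies adjacent segment swaps —
#' letting the other rows re-sort in response — while the total crossing
#' count strictly decreases. The cycle repeats until the segment orders
#' reach a fixed point, and the result is never worse than the input, so
#' applying the operation twice equals applying it once.
#'
#' @param layout a `parallel_sets_layout`.
#' @param max_pass safety cap on convergence passes.
#' @param polish_limit largest group count on which the local-search
#'   polish runs (it is quadratic in the number of bands).
#' @param exact_limit exhaustive-search budget for small instances.
#' @return The layout with updated within-bar segment orders.
#' @export
rearrange_bands <- function(layout, max_pass = 25L, polish_limit = 15L,
                            exact_limit = 5000) {
  stopifnot(inherits(layout, "parallel_sets_layout"))
  R <- length(layout$row_order)
  if (R < 2L) return(layout)
  frozen_all <- layout
  frozen_all$frozen <- layout$row_order
  if (enum_budget(frozen_all) <= exact_limit) {
    best <- exact_min_layout(frozen_all)
    layout$seg_order <- best$seg_order
    return(layout)
  }
  entry <- layout
  entry_cc <- count_crossings(layout)
  do_polish <- length(layout$group_sizes) <= polish_limit
  sort_segments <- function(layout, id, ref_id) {
    refmid <- fast_midpoints(layout, ref_id)
    changed <- FALSE
    for (lab in names(layout$seg_order[[id]])) {
      gidx <- layout$seg_order[[id]][[lab]]
      if (length(gidx) < 2L) next
      key <- refmid[gidx]
      key[is.na(key)] <- Inf
      neword <- gidx[order(key, layout$signatures[gidx])]
      if (!identical(neword, gidx)) {
        layout$seg_order[[id]][[lab]] <- neword
        changed <- TRUE
      }
    }
    attr(layout, "changed") <- changed
    layout
  }
  relax_others <- function(layout, id) {
    # barycenter re-sort of every row except `id`, top-down
    if (layout$row_order[1L] != id)
      layout <- sort_segments(layout, layout$row_order[1L],
                              layout$row_order[2L])
    for (ri in seq(2L, R))
      if (layout$row_order[ri] != id)
        layout <- sort_segments(layout, layout$row_order[ri],
                                layout$row_order[ri - 1L])
    layout
  }
  polish <- function(layout) {
    changed <- FALSE
    repeat {
      improved <- FALSE
      base <- count_crossings(layout)
      for (id in layout$row_order) {
        for (lab in names(layout$seg_order[[id]])) {
          gidx <- layout$seg_order[[id]][[lab]]
          if (length(gidx) < 2L) next
          for (i in seq_len(length(gidx) - 1L)) {
            trial <- layout
            trial$seg_order[[id]][[lab]][c(i, i + 1L)] <-
              trial$seg_order[[id]][[lab]][c(i + 1L, i)]
            # let the other rows follow the swap before judging it
            trial <- relax_others(trial, id)
            cc <- count_crossings(trial)
            if (cc < base) {
              layout <- trial; base <- cc
              improved <- TRUE; changed <- TRUE
            }
          }
        }
      }
      if (!improved) break
    }
    attr(layout, "changed") <- changed
    layout
  }
  for (pass in seq_len(max_pass)) {
    any_change <- FALSE
    layout <- sort_segments(layout, layout$row_order[1L],
                            layout$row_order[2L])
    any_change <- any_change || attr(layout, "changed")
    for (ri in seq(2L, R)) {
      layout <- sort_segments(layout, layout$row_order[ri],
                              layout$row_order[ri - 1L])
      any_change <- any_change || attr(layout, "changed")
    }
    if (do_polish) {
      layout <- polish(layout)
      any_change <- any_change || attr(layout, "changed")
    }
    if (!any_change) break
  }
  attr(layout, "changed") <- NULL
  if (count_crossings(layout) > entry_cc) return(entry)
  layout
}

#' Serialize a layout's geometry to JSON
#' @param layout a `parallel_sets_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  geom <- layout_geometry(layout)
  obj <- list(W = layout$W, gap = layout$gap, height = geom$height,
              rows = lapply(layout$row_order, function(id)
                list(result_id = id, y = geom$rows[[id]]$y,
                     bars = geom$rows[[id]]$bars,
                     segments = geom$rows[[id]]$segs)))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
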