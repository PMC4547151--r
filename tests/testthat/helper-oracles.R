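# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. Every oracle deliberately takes a
# different computational route than the package implementation.

# Build a clustering_result from a plain label vector.
cr_from_labels <- function(labels, id = "r", ids = NULL,
                           noise_label = NULL) {
  if (is.null(ids)) ids <- sprintf("i%03d", seq_along(labels))
  clustering_result(id, "fixture", list(),
                    stats::setNames(as.character(labels), ids),
                    noise_label = noise_label)
}

# Small expression matrix fixture with fixed values; existing dimnames
# are kept.
tiny_matrix <- function(values, ids = NULL, conds = NULL) {
  if (is.null(ids))
    ids <- if (!is.null(rownames(values))) rownames(values)
           else sprintf("g%d", seq_len(nrow(values)))
  if (is.null(conds))
    conds <- if (!is.null(colnames(values))) colnames(values)
             else sprintf("c%d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, conds)
  expression_matrix(values)
}

# --- pair-counting oracle ------------------------------------------------

# Explicit enumeration of co-clustered unordered pairs as "i<j" strings.
oracle_pair_set <- function(r, include_noise = TRUE) {
  out <- character()
  for (lab in names(r$clusters)) {
    if (!include_noise && identical(lab, r$noise_label)) next
    mem <- sort(r$clusters[[lab]])
    if (length(mem) < 2L) next
    pr <- utils::combn(mem, 2L)
    out <- c(out, paste(pr[1L, ], pr[2L, ], sep = "\r"))
  }
  out
}

oracle_f_measure <- function(a, b, include_noise = TRUE) {
  pa <- oracle_pair_set(a, include_noise)
  pb <- oracle_pair_set(b, include_noise)
  if (length(pa) == 0L && length(pb) == 0L) return(1)
  if (length(pa) == 0L || length(pb) == 0L) return(0)
  agreed <- length(intersect(pa, pb))
  prec <- agreed / length(pa)
  rec <- agreed / length(pb)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# All set partitions of n items as restricted-growth label vectors.
all_set_partitions <- function(n) {
  parts <- list(c(1L))
  for (i in seq_len(n - 1L)) {
    parts <- unlist(lapply(parts, function(p) {
      mx <- max(p)
      lapply(seq_len(mx + 1L), function(l) c(p, l))
    }), recursive = FALSE)
  }
  parts
}

# --- meet-partition oracle ----------------------------------------------

# Groups items by their membership vector, located by scanning each
# result's cluster member lists (not its assignment vector).
oracle_stable_groups <- function(results) {
  items <- sort(names(results[[1L]]$assignment))
  sig <- vapply(items, function(it) {
    paste(vapply(results, function(r) {
      hit <- which(vapply(r$clusters, function(mem) it %in% mem,
                          logical(1L)))
      as.character(hit)
    }, character(1L)), collapse = "/")
  }, character(1L))
  unname(split(items, sig))
}

# Canonical form of a list of item groups for set-of-sets equality.
canon_groups <- function(groups)
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1L))))

# --- OPTICS oracle -------------------------------------------------------

# Direct translation of the textbook OPTICS pseudocode with an explicit
# order-seeds list, kept structurally different from the package
# implementation. Neighborhoods include the point itself; ties in the
# seed list break toward the smaller row index.
oracle_optics <- function(x, min_pts, eps = Inf) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  core_of <- function(i) {
    nd <- sort(d[i, d[i, ] <= eps])
    if (length(nd) >= min_pts) nd[min_pts] else Inf
  }
  processed <- rep(FALSE, n)
  ordering <- integer(0)
  reach_out <- numeric(0)
  seeds <- list()   # named list index -> reachability
  pop_seed <- function() {
    idx <- as.integer(names(seeds))
    vals <- unlist(seeds)
    best <- idx[order(vals, idx)][1L]
    best
  }
  for (p in seq_len(n)) {
    if (processed[p]) next
    processed[p] <- TRUE
    ordering <- c(ordering, p); reach_out <- c(reach_out, Inf)
    cd <- core_of(p)
    if (is.finite(cd)) {
      for (o in which(d[p, ] <= eps & !processed)) {
        nr <- max(cd, d[p, o])
        key <- as.character(o)
        if (is.null(seeds[[key]]) || nr < seeds[[key]])
          seeds[[key]] <- nr
      }
      while (length(seeds) > 0L) {
        q <- pop_seed()
        rq <- seeds[[as.character(q)]]
        seeds[[as.character(q)]] <- NULL
        processed[q] <- TRUE
        ordering <- c(ordering, q); reach_out <- c(reach_out, rq)
        cq <- core_of(q)
        if (is.finite(cq)) {
          for (o in which(d[q, ] <= eps & !processed)) {
            nr <- max(cq, d[q, o])
            key <- as.character(o)
            if (is.null(seeds[[key]]) || nr < seeds[[key]])
              seeds[[key]] <- nr
          }
        }
      }
    }
  }
  list(ordering = ordering, reachability = reach_out)
}

# --- layout helpers ------------------------------------------------------

# Random multi-result comparison instance over a planted matrix.
random_instance <- function(n_items, n_results, k_range = 2:4, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("i%03d", seq_len(n_items))
  results <- lapply(seq_len(n_results), function(j) {
    k <- sample(k_range, 1L)
    labels <- sprintf("C%d", sample.int(k, n_items, replace = TRUE))
    cr_from_labels(labels, id = sprintf("R%d", j), ids = ids)
  })
  results
}

# Independent crossing count: recomputes segment midpoints directly from
# the stored orders by cumulative sums, then counts inversions pairwise.
oracle_crossings <- function(layout) {
  n_items <- sum(layout$group_sizes)
  mids_of_row <- function(id) {
    ord <- layout$bar_order[[id]]
    scale <- (layout$W - layout$gap * (length(ord) - 1L)) / n_items
    mids <- rep(NA_real_, length(layout$group_sizes))
    x <- 0
    for (lab in ord) {
      for (g in layout$seg_order[[id]][[lab]]) {
        w <- layout$group_sizes[g] * scale
        mids[g] <- x + w / 2
        x <- x + w
      }
      x <- x + layout$gap
    }
    mids
  }
  vis <- which(layout$visible)
  total <- 0L
  for (ri in seq_len(length(layout$row_order) - 1L)) {
    m1 <- mids_of_row(layout$row_order[ri])[vis]
    m2 <- mids_of_row(layout$row_order[ri + 1L])[vis]
    if (length(vis) >= 2L) {
      pr <- utils::combn(seq_along(vis), 2L)
      total <- total + sum((m1[pr[1L, ]] - m1[pr[2L, ]]) *
                             (m2[pr[1L, ]] - m2[pr[2L, ]]) < 0)
    }
  }
  as.integer(total)
}

# Exhaustive minimum crossing count over all bar orders per row and all
# within-bar segment orders; only for tiny instances.
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

optimal_crossings <- function(layout, max_combos = 3e5) {
  rows <- layout$row_order
  per_row <- lapply(rows, function(id) {
    bar_perms <- perms(layout$bar_order[[id]])
    combos <- list()
    for (bp in bar_perms) {
      seg_perm_lists <- lapply(bp, function(lab)
        perms(layout$seg_order[[id]][[lab]]))
      grid <- seg_perm_lists[[1L]]
      grid <- lapply(grid, list)
      if (length(bp) > 1L) for (bi in seq(2L, length(bp))) {
        grid <- unlist(lapply(grid, function(g)
          lapply(seg_perm_lists[[bi]], function(sp) c(g, list(sp)))),
          recursive = FALSE)
      }
      for (g in grid)
        combos[[length(combos) + 1L]] <-
          list(bars = bp, segs = stats::setNames(g, bp))
    }
    combos
  })
  total <- prod(vapply(per_row, length, numeric(1L)))
  stopifnot(total <= max_combos)
  best <- Inf
  idx <- rep(1L, length(rows))
  repeat {
    trial <- layout
    for (ri in seq_along(rows)) {
      cmb <- per_row[[ri]][[idx[ri]]]
      trial$bar_order[[rows[ri]]] <- cmb$bars
      trial$seg_order[[rows[ri]]] <- cmb$segs
    }
    best <- min(best, oracle_crossings(trial))
    if (best == 0L) return(0L)
    ri <- 1L
    while (ri <= length(rows)) {
      idx[ri] <- idx[ri] + 1L
      if (idx[ri] <= length(per_row[[ri]])) break
      idx[ri] <- 1L; ri <- ri + 1L
    }
    if (ri > length(rows)) break
  }
  as.integer(best)
}

# Circular hue distance in degrees.
hue_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# --- tree-colors helpers -------------------------------------------------

# Hand-built balanced cluster hierarchy over 2^depth pseudo-clusters with
# randomly permuted leaves, for structural color-assignment checks.
balanced_cluster_tree <- function(depth, seed = 1L) {
  n <- 2L^depth
  set.seed(seed)
  perm <- sample.int(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  prev <- -perm
  row <- 0L; lvl <- 1L
  while (length(prev) > 1L) {
    cur <- integer(0)
    for (i in seq(1L, length(prev), by = 2L)) {
      row <- row + 1L
      merge[row, ] <- c(prev[i], prev[i + 1L])
      height[row] <- 0.1 * lvl
      cur <- c(cur, row)
    }
    prev <- cur; lvl <- lvl + 1L
  }
  info <- data.frame(cluster_id = sprintf("L%d", seq_len(n)),
                     result_id = "r", label = sprintf("L%d", seq_len(n)),
                     size = 1L, is_noise = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(info = info,
                 centroids = matrix(stats::rnorm(n * 3), n),
                 hclust = list(merge = merge, height = height,
                               labels = info$cluster_id,
                               order = seq_len(n))),
            class = "cluster_tree")
}

# Leaf sets below every internal node of a merge matrix.
node_leaf_sets <- function(merge) {
  out <- vector("list", nrow(merge))
  get <- function(v) if (v < 0L) -v else out[[v]]
  for (i in seq_len(nrow(merge)))
    out[[i]] <- c(get(merge[i, 1L]), get(merge[i, 2L]))
  out
}

# Depth (root = 0) of every internal node.
node_depths <- function(merge) {
  nd <- integer(nrow(merge))
  assign_depth <- function(v, d) {
    if (v < 0L) return(invisible())
    nd[v] <<- d
    assign_depth(merge[v, 1L], d + 1L)
    assign_depth(merge[v, 2L], d + 1L)
  }
  assign_depth(nrow(merge), 0L)
  nd
}
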