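#' Row standardization for the correlation metric
#'
#' Pearson-style distances in a k-means loop break the mean-centroid
#' update, so the correlation metric is realized as Euclidean k-means on
#' row-standardized profiles (each row centered to mean 0 and scaled to
#' unit norm): squared Euclidean distance between standardized rows is
#' then monotone in 1 - Pearson correlation.
#' @noRd
standardize_rows <- function(x) {
  x <- sweep(x, 1L, rowMeans(x))
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  sweep(x, 1L, nrm, "/")
}

#' Greedy farthest-point (k-means++-style) center seeding: first center
#' drawn from the seeded RNG, each further center the point with maximal
#' distance to its nearest chosen center (first index on ties).
#' @noRd
seed_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
    for (i in seq(2L, k)) {
      centers[i] <- which.max(d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[i], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of an expression matrix
#'
#' Lloyd-style k-means (via [stats::kmeans()]) from greedy farthest-point
#' seeding, deterministic for a fixed seed. One call is one run; repeated
#' runs with other seeds are registered as separate results, mirroring the
#' explore-many-results workflow.
#'
#' @param m an `expr_matrix`.
#' @param k number of clusters, `1 <= k <=` number of items.
#' @param metric `"euclidean"` or `"correlation"` (Euclidean k-means on
#'   row-standardized profiles).
#' @param seed integer RNG seed.
#' @param result_id identifier; a descriptive default is generated.
#' @return A [clustering_result()] with at most `k` non-empty clusters
#'   labelled `C1..Ck` and params recording metric, k and seed.
#' @export
run_kmeans <- function(m, k, metric = c("euclidean", "correlation"),
                       seed = 1L,
                       result_id = sprintf("KMeans(k=%d,%s,seed=%d)",
                                           k, match.arg(metric), seed)) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "expr_matrix"))
  n <- nrow(m$values)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds the number of items (", n, ")",
                  call. = FALSE)
  x <- if (metric == "correlation") standardize_rows(m$values) else m$values
  set.seed(seed)
  init <- seed_centers(x, k)
  fit <- if (k == 1L)
    list(cluster = rep(1L, n))
  else tryCatch(
    stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"),
    error = function(e)
      stats::kmeans(x, centers = init, iter.max = 100L,
                    algorithm = "MacQueen"),
    warning = function(w)
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 200L,
                                     algorithm = "Lloyd")))
  lab <- fit$cluster
  # relabel to C1..Ck in order of first appearance, dropping empty clusters
  lab <- match(lab, unique(lab))
  assignment <- stats::setNames(sprintf("C%d", lab), item_ids(m))
  clustering_result(result_id, "kmeans",
                    params = list(metric = metric, k = k, seed = seed),
                    assignment = assignment)
}

#' Deterministic dendrogram leaf order: at each merge the subtree whose
#' minimum original row index is smaller goes left.
#' @noRd
reorder_hclust <- function(hc) {
  n <- length(hc$labels)
  minidx <- vector("list", nrow(hc$merge))
  leaves <- vector("list", nrow(hc$merge))
  getm <- function(v) if (v < 0L) -v else minidx[[v]]
  getl <- function(v) if (v < 0L) -v else leaves[[v]]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1L]; b <- hc$merge[i, 2L]
    ma <- min(getm(a)); mb <- min(getm(b))
    if (ma <= mb) {
      minidx[[i]] <- c(getm(a), getm(b))
      leaves[[i]] <- c(getl(a), getl(b))
      hc$merge[i, ] <- c(a, b)
    } else {
      minidx[[i]] <- c(getm(b), getm(a))
      leaves[[i]] <- c(getl(b), getl(a))
      hc$merge[i, ] <- c(b, a)
    }
  }
  hc$order <- leaves[[nrow(hc$merge)]]
  hc
}

#' Hierarchical agglomerative clustering of items
#'
#' HAC over the rows of an expression matrix. Merge heights are converted
#' to a similarity scale so a "minimum similarity bar" can cut the
#' dendrogram: for the correlation metric similarity = 1 - distance (so it
#' lives in [-1, 1]); for Euclidean distances similarity = 1 - h / h_max,
#' a normalized [0, 1] scale. Leaf order is deterministic: at each merge
#' the subtree containing the smaller original row index is placed left.
#'
#' @param m an `expr_matrix` with at least two rows.
#' @param metric `"euclidean"` or `"correlation"` (distance
#'   `1 - Pearson r` between rows).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An object of class `hclust_result`: the [stats::hclust()] tree
#'   plus the per-merge similarity scale.
#' @export
hac_items <- function(m, metric = c("euclidean", "correlation"),
                      linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) < 2L)
    stop("need at least 2 items to build a hierarchy", call. = FALSE)
  d <- if (metric == "euclidean") stats::dist(m$values)
       else stats::as.dist(1 - suppressWarnings(stats::cor(t(m$values))))
  if (anyNA(d)) {
    # zero-variance rows have undefined correlation; treat as unrelated
    dm <- as.matrix(d); dm[is.na(dm)] <- 1; diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  hc <- reorder_hclust(stats::hclust(d, method = linkage))
  hmax <- max(hc$height)
  sim <- if (metric == "correlation") 1 - hc$height
         else if (hmax > 0) 1 - hc$height / hmax else rep(1, length(hc$height))
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 merge_similarity = sim,
                 labels = item_ids(m)),
            class = "hclust_result")
}

#' @export
print.hclust_result <- function(x, ...) {
  cat(sprintf("<hclust_result> %d leaves, %s metric, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  invisible(x)
}

#' Cut a dendrogram at a minimum similarity
#'
#' Clusters are the maximal subtrees whose internal merges all reach
#' similarity `s` — the batch version of dragging a minimum similarity bar
#' across a dendrogram. Extreme thresholds are legal: below every merge
#' similarity the result is one cluster, above all of them all singletons.
#'
#' @param hr an `hclust_result`.
#' @param s similarity threshold on the result's similarity scale.
#' @param result_id identifier for the derived result.
#' @return A [clustering_result()] with `algorithm = "hac"`.
#' @export
cut_by_similarity <- function(hr, s,
                              result_id = sprintf("HAC(%s,%s,s=%g)",
                                                  hr$metric, hr$linkage, s)) {
  stopifnot(inherits(hr, "hclust_result"))
  hc <- hr$hclust
  hmax <- max(hc$height)
  h <- if (hr$metric == "correlation") 1 - s
       else (1 - s) * (if (hmax > 0) hmax else 1)
  memb <- if (h < min(hc$height) - 1e-12)
    stats::setNames(seq_along(hr$labels), hr$labels)
  else
    stats::cutree(hc, h = h + 1e-12)
  lab <- match(memb, unique(memb[hc$order]))  # label in leaf order
  assignment <- stats::setNames(sprintf("C%d", lab), hr$labels)
  clustering_result(result_id, "hac",
                    params = list(metric = hr$metric, linkage = hr$linkage,
                                  similarity = s),
                    assignment = assignment)
}

#' Session registry of clustering results
#'
#' Holds all results generated in an analysis session and aggregates how
#' often each algorithm/parameter setting was used (the basis of the
#' parameter-information bar charts). The canonical setting excludes the
#' seed, so re-runs of a non-deterministic algorithm with identical
#' settings accumulate in one count.
#'
#' @return An empty registry of class `session_registry`.
#' @export
session_registry <- function() {
  structure(list(results = list()), class = "session_registry")
}

#' @rdname session_registry
#' @param reg a `session_registry`.
#' @param r a `clustering_result` whose `result_id` is not yet registered.
#' @export
register <- function(reg, r) {
  stopifnot(inherits(reg, "session_registry"),
            inherits(r, "clustering_result"))
  if (r$result_id %in% names(reg$results))
    stop("duplicate result_id: ", r$result_id, call. = FALSE)
  reg$results[[r$result_id]] <- r
  reg
}

#' Canonical parameter setting: sorted name=value pairs, seed excluded.
#' @noRd
canonical_setting <- function(params) {
  params <- params[setdiff(names(params), "seed")]
  if (length(params) == 0L) return("")
  params <- params[order(names(params))]
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(v) paste(format(v), collapse = ","),
                       character(1L))),
        collapse = ", ")
}

#' @rdname session_registry
#' @export
parameter_counts <- function(reg) {
  stopifnot(inherits(reg, "session_registry"))
  if (length(reg$results) == 0L)
    return(data.frame(algorithm = character(), setting = character(),
                      count = integer()))
  alg <- vapply(reg$results, `[[`, character(1L), "algorithm")
  set <- vapply(reg$results, function(r) canonical_setting(r$params),
                character(1L))
  tab <- table(algorithm = alg, setting = set)
  df <- as.data.frame(tab, stringsAsFactors = FALSE,
                      responseName = "count")
  df <- df[df$count > 0L, ]
  df <- df[order(df$algorithm, df$setting), ]
  rownames(df) <- NULL
  df$count <- as.integer(df$count)
  df
}

#' @export
print.session_registry <- function(x, ...) {
  cat(sprintf("<session_registry> %d results\n", length(x$results)))
  invisible(x)
}
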