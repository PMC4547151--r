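#' Aligned label matrix for a set of clustering results
#'
#' Returns an items-by-results character matrix of cluster labels, after
#' checking that all results cover the same items (or restricting to the
#' common intersection when `restrict = TRUE`, for comparing externally
#' imported results against internally computed ones).
#' @noRd
aligned_labels <- function(results, restrict = FALSE) {
  stopifnot(length(results) >= 1L)
  for (r in results) stopifnot(inherits(r, "clustering_result"))
  sets <- lapply(results, function(r) names(r$assignment))
  if (all(vapply(sets[-1L], identical, logical(1L), sets[[1L]]))) {
    # fast path: identical item vectors in identical order
    out <- vapply(results, function(r) unname(r$assignment),
                  character(length(sets[[1L]])))
    return(matrix(out, nrow = length(sets[[1L]]),
                  dimnames = list(sets[[1L]],
                                  vapply(results, `[[`, character(1L),
                                         "result_id"))))
  }
  common <- Reduce(intersect, sets)
  if (!restrict) {
    for (i in seq_along(sets)) {
      extra <- setdiff(sets[[i]], common)
      miss <- setdiff(common, sets[[i]])
      if (length(extra) || length(miss)) {
        all_union <- Reduce(union, sets)
        diffs <- setdiff(all_union, common)
        stop("results cover different item sets; symmetric difference: ",
             paste(utils::head(sort(diffs), 10L), collapse = ", "),
             if (length(diffs) > 10L) ", ...",
             " (use restrict = TRUE to compare on the intersection)",
             call. = FALSE)
      }
    }
  }
  if (length(common) == 0L)
    stop("results share no items", call. = FALSE)
  common <- sort(common)
  out <- vapply(results, function(r) unname(r$assignment[common]),
                character(length(common)))
  matrix(out, nrow = length(common),
         dimnames = list(common, vapply(results, `[[`, character(1L),
                                        "result_id")))
}

#' Number of co-clustered item pairs in a result
#'
#' The size of the result's pair set: the number of unordered item pairs
#' that share a cluster. The noise cluster's internal pairs count by
#' default (the noise group is treated as one special cluster); set
#' `include_noise = FALSE` to exclude them.
#'
#' @param r a `clustering_result`.
#' @param include_noise count pairs inside the noise cluster?
#' @return Non-negative count.
#' @export
copair_count <- function(r, include_noise = TRUE) {
  stopifnot(inherits(r, "clustering_result"))
  sizes <- cluster_sizes(r)
  if (!include_noise && !is.na(r$noise_label))
    sizes <- sizes[names(sizes) != r$noise_label]
  sum(choose(sizes, 2))
}

#' Pair-counting F-measure between two clustering results
#'
#' An agreed pair is an unordered item pair co-clustered in both results.
#' Precision and recall each divide the number of agreed pairs by one
#' result's total co-clustered pair count; the F-measure is their harmonic
#' mean, so it is symmetric in the two results and equals 1 exactly when
#' the partitions are identical up to label renaming. Degenerate cases:
#' if both pair sets are empty (both partitions all-singletons) F is 1;
#' if exactly one is empty F is 0.
#'
#' @param a,b `clustering_result`s over the same item set.
#' @param include_noise count pairs inside a noise cluster? Default TRUE.
#' @param restrict compare on the intersection of the item sets instead of
#'   erroring on a mismatch.
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(a, b, include_noise = TRUE, restrict = FALSE) {
  lab <- aligned_labels(list(a, b), restrict = restrict)
  la <- lab[, 1L]; lb <- lab[, 2L]
  keep_a <- if (!include_noise && !is.na(a$noise_label))
    la != a$noise_label else rep(TRUE, length(la))
  keep_b <- if (!include_noise && !is.na(b$noise_label))
    lb != b$noise_label else rep(TRUE, length(lb))
  pa <- sum(choose(table(la[keep_a]), 2))
  pb <- sum(choose(table(lb[keep_b]), 2))
  agreed <- sum(choose(table(la[keep_a & keep_b], lb[keep_a & keep_b]), 2))
  if (pa == 0 && pb == 0) return(1)
  if (pa == 0 || pb == 0) return(0)
  prec <- agreed / pa
  rec <- agreed / pb
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Pairwise F-measure similarity matrix
#'
#' @param results list of at least two `clustering_result`s over the same
#'   item set.
#' @param include_noise,restrict passed to [f_measure()].
#' @return Symmetric numeric matrix of class `similarity_matrix` with unit
#'   diagonal, dimnames = result IDs.
#' @export
similarity_matrix <- function(results, include_noise = TRUE,
                              restrict = FALSE) {
  stopifnot(length(results) >= 2L)
  ids <- vapply(results, `[[`, character(1L), "result_id")
  if (anyDuplicated(ids))
    stop("duplicate result_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  k <- length(results)
  sm <- diag(1, k)
  dimnames(sm) <- list(ids, ids)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    f <- f_measure(results[[i]], results[[j]],
                   include_noise = include_noise, restrict = restrict)
    sm[i, j] <- f; sm[j, i] <- f
  }
  class(sm) <- c("similarity_matrix", class(sm))
  sm
}

#' Pearson correlation between two cluster centroids
#'
#' The cluster-to-cluster similarity used for the global cluster
#' hierarchy, band rearrangement and cluster-graph edge weights. A
#' zero-variance centroid (a flat mean profile) has undefined
#' correlation; it is reported as 0 with a warning.
#'
#' @param centroid1,centroid2 numeric profiles over the same conditions
#'   (length >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
centroid_correlation <- function(centroid1, centroid2) {
  if (length(centroid1) != length(centroid2))
    stop("centroids differ in length", call. = FALSE)
  if (length(centroid1) < 2L)
    stop("need at least 2 conditions for a correlation", call. = FALSE)
  if (stats::sd(centroid1) == 0 || stats::sd(centroid2) == 0) {
    warning("zero-variance centroid; correlation set to 0")
    return(0)
  }
  stats::cor(centroid1, centroid2)
}

#' @rdname centroid_correlation
#' @param c1,c2 clusters given as `list(result =, label =)` pairs.
#' @param m the `expr_matrix` both results were computed on.
#' @export
cluster_correlation <- function(c1, c2, m) {
  centroid_correlation(cluster_centroid(c1$result, c1$label, m),
                       cluster_centroid(c2$result, c2$label, m))
}

#' Stable groups: the meet of several partitions
#'
#' A stable group is a maximal set of items clustered together in every
#' selected result — a block of the meet (greatest common refinement) of
#' the partitions. Items are grouped by their membership signature, the
#' tuple of cluster labels across the source results; groups are ordered
#' by descending size, then by signature.
#'
#' @param results non-empty list of `clustering_result`s.
#' @param restrict compare on the intersection of item sets.
#' @return An object of class `stable_group_set`: `groups` (list of item
#'   ID vectors), `signatures` (one per group, `label1 | label2 | ...` in
#'   result order), `result_ids`, and a `visible` logical vector
#'   manipulated by [filter_groups()].
#' @export
stable_groups <- function(results, restrict = FALSE) {
  if (length(results) == 0L)
    stop("need at least one clustering result", call. = FALSE)
  lab <- aligned_labels(results, restrict = restrict)
  sig <- apply(lab, 1L, paste, collapse = " | ")
  groups <- split(rownames(lab), sig)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  structure(list(groups = unname(groups),
                 signatures = names(groups),
                 result_ids = colnames(lab),
                 visible = rep(TRUE, length(groups))),
            class = "stable_group_set")
}

#' @export
print.stable_group_set <- function(x, ...) {
  cat(sprintf(
    "<stable_group_set> %d groups over %d items from %d results (%d visible)\n",
    length(x$groups), sum(lengths(x$groups)), length(x$result_ids),
    sum(x$visible)))
  invisible(x)
}

#' Band-size filtering of stable groups
#'
#' Marks groups outside `[min_size, max_size]` as hidden. Filtering is a
#' rendering concern only: the partition itself is untouched, and layouts
#' built from the filtered set leave proportional blank space where hidden
#' bands would run.
#'
#' @param sgs a `stable_group_set`.
#' @param min_size,max_size inclusive size bounds, `1 <= min <= max`.
#' @return The `stable_group_set` with an updated `visible` vector.
#' @export
filter_groups <- function(sgs, min_size = 1L, max_size = Inf) {
  stopifnot(inherits(sgs, "stable_group_set"))
  if (min_size < 1L || min_size > max_size)
    stop("need 1 <= min_size <= max_size", call. = FALSE)
  sz <- lengths(sgs$groups)
  sgs$visible <- sz >= min_size & sz <= max_size
  sgs
}

#' @rdname filter_groups
#' @return `group_histogram()` returns a named integer vector mapping
#'   group size to the number of groups of that size.
#' @export
group_histogram <- function(sgs) {
  stopifnot(inherits(sgs, "stable_group_set"))
  tab <- table(lengths(sgs$groups))
  stats::setNames(as.integer(tab), names(tab))
}

#' Serialize stable groups to JSON
#' @param sgs a `stable_group_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stable_groups <- function(sgs, path) {
  stopifnot(inherits(sgs, "stable_group_set"))
  obj <- list(result_ids = sgs$result_ids,
              groups = lapply(seq_along(sgs$groups), function(i)
                list(signature = sgs$signatures[i],
                     size = length(sgs$groups[[i]]),
                     visible = sgs$visible[i],
                     items = sgs$groups[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a similarity matrix to CSV
#' @param sm a `similarity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sm, path) {
  df <- data.frame(result_id = rownames(sm),
                   as.data.frame(unclass(sm), check.names = FALSE),
                   check.names = FALSE)
  # result ids may contain commas; quote all character fields
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}
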