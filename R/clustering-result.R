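#' Clustering result container
#'
#' A `clustering_result` is one partition of an item set, with provenance:
#' which algorithm produced it and under which parameters. Clusters are
#' stored in deterministic order (label sort order, noise cluster last).
#' At most one cluster may be flagged as the noise cluster — the single
#' pseudo-cluster collecting items a density-based algorithm left
#' unassigned. Treating those items as one special cluster (rather than
#' singletons) keeps downstream stable-group extraction readable.
#'
#' @param result_id unique identifier, e.g. `"KMeans Clustering(5)"`.
#' @param algorithm algorithm name (`"kmeans"`, `"hac"`, `"som"`,
#'   `"optics"`, `"imported"`, ...).
#' @param params named list of parameter values (distance metric, cluster
#'   count, seed, ...).
#' @param assignment named character vector mapping item ID to cluster
#'   label; names must be unique.
#' @param noise_label label of the noise cluster, or `NULL` when there is
#'   none.
#' @param extra named list of algorithm-specific payload carried along
#'   (e.g. OPTICS cluster span positions).
#' @return An object of class `clustering_result`.
#' @export
clustering_result <- function(result_id, algorithm, params, assignment,
                              noise_label = NULL, extra = list()) {
  stopifnot(is.character(result_id), length(result_id) == 1L,
            is.character(algorithm), length(algorithm) == 1L,
            is.list(params))
  items <- names(assignment)
  if (is.null(items) || anyDuplicated(items))
    stop("assignment must be named by unique item IDs", call. = FALSE)
  if (length(assignment) == 0L)
    stop("assignment is empty", call. = FALSE)
  if (anyNA(assignment)) stop("cluster labels must not be NA", call. = FALSE)
  labels <- sort(unique(unname(assignment)))
  if (!is.null(noise_label)) {
    if (!noise_label %in% labels)
      stop("noise label ", noise_label, " has no members", call. = FALSE)
    labels <- c(setdiff(labels, noise_label), noise_label)
  }
  clusters <- lapply(labels, function(l) items[assignment == l])
  names(clusters) <- labels
  # partition invariant: pairwise disjoint with union = items, by splitting
  stopifnot(sum(lengths(clusters)) == length(items))
  structure(list(result_id = result_id, algorithm = algorithm,
                 params = params,
                 assignment = assignment,
                 clusters = clusters,
                 noise_label = if (is.null(noise_label)) NA_character_
                               else noise_label,
                 extra = extra),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s [%s]: %d items, %d clusters%s\n",
              x$result_id, x$algorithm, length(x$assignment),
              length(x$clusters),
              if (!is.na(x$noise_label))
                sprintf(" (noise: %s, %d items)", x$noise_label,
                        length(x$clusters[[x$noise_label]]))
              else ""))
  invisible(x)
}

#' Cluster sizes of a result
#' @param r a `clustering_result`.
#' @return Named integer vector of member counts per cluster.
#' @export
cluster_sizes <- function(r) {
  stopifnot(inherits(r, "clustering_result"))
  vapply(r$clusters, length, integer(1L))
}

#' Mean expression profile of a cluster
#'
#' @param r a `clustering_result`.
#' @param label a cluster label of `r`.
#' @param m the `expr_matrix` the result was computed on.
#' @return Numeric vector, one mean per condition column.
#' @export
cluster_centroid <- function(r, label, m) {
  stopifnot(inherits(r, "clustering_result"), inherits(m, "expr_matrix"))
  members <- r$clusters[[label]]
  if (is.null(members)) stop("no cluster labelled ", label, call. = FALSE)
  missing <- setdiff(members, item_ids(m))
  if (length(missing))
    stop("cluster members missing from matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  colMeans(m$values[members, , drop = FALSE])
}

#' Import externally produced cluster assignments
#'
#' Reads a two-column CSV (`item,cluster`; an optional third column is
#' ignored, a header line starting with `item` is skipped). Items of the
#' universe absent from the file, and rows labelled with `noise_label`,
#' are collected into a single noise cluster, so external partial
#' clusterings compare cleanly against internally computed ones.
#'
#' @param path assignment CSV path.
#' @param item_universe character vector of all item IDs in play.
#' @param noise_label optional label in the file marking unassigned items.
#' @param result_id identifier for the imported result.
#' @return A [clustering_result()] with `algorithm = "imported"`.
#' @export
import_assignments <- function(path, item_universe, noise_label = NULL,
                               result_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty assignment file: ", path,
                                call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (tolower(trimws(parts[[1L]][1L])) == "item") parts <- parts[-1L]
  if (length(parts) == 0L) stop("no assignment rows in ", path, call. = FALSE)
  items <- vapply(parts, function(p) trimws(p[1L]), character(1L))
  labs <- vapply(parts, function(p) {
    if (length(p) < 2L) stop("row without a cluster label: ",
                             paste(p, collapse = ","), call. = FALSE)
    trimws(p[2L])
  }, character(1L))
  unknown <- setdiff(items, item_universe)
  if (length(unknown))
    stop("unknown item ID: ", unknown[1L], call. = FALSE)
  if (anyDuplicated(items)) {
    for (it in unique(items[duplicated(items)])) {
      l <- unique(labs[items == it])
      if (length(l) > 1L)
        stop("item ", it, " listed twice with different labels (",
             paste(l, collapse = " vs "), ")", call. = FALSE)
    }
    keep <- !duplicated(items)
    items <- items[keep]; labs <- labs[keep]
  }
  noise <- "(unclustered)"
  if (!is.null(noise_label)) labs[labs == noise_label] <- noise
  assignment <- stats::setNames(labs, items)
  rest <- setdiff(item_universe, items)
  if (length(rest))
    assignment <- c(assignment, stats::setNames(rep(noise, length(rest)),
                                                rest))
  assignment <- assignment[item_universe]  # universe order
  has_noise <- noise %in% assignment
  clustering_result(result_id, "imported",
                    params = list(source = basename(path)),
                    assignment = assignment,
                    noise_label = if (has_noise) noise else NULL)
}

#' Serialize a clustering result to CSV + JSON sidecar
#'
#' Writes the assignment table (`item,cluster`) plus a JSON sidecar with
#' result id, algorithm, parameters and noise label.
#'
#' @param r a `clustering_result`.
#' @param path CSV output path; the sidecar gets the extension `.json`.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(r, path) {
  stopifnot(inherits(r, "clustering_result"))
  df <- data.frame(item = names(r$assignment),
                   cluster = unname(r$assignment))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(result_id = r$result_id, algorithm = r$algorithm,
               params = r$params,
               noise_label = if (is.na(r$noise_label)) NULL else
                 r$noise_label)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
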