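#' OPTICS density-based ordering
#'
#' Standard OPTICS over the rows of an expression matrix with Euclidean
#' distances. The epsilon-neighborhood of a point includes the point
#' itself, so with `min_pts = 2` the core distance is the distance to the
#' nearest other point. Ties in the seed queue are broken toward the
#' smaller original row index and unprocessed start points are taken in
#' row order, making the ordering fully deterministic.
#'
#' @param m an `expr_matrix`.
#' @param min_pts minimum neighborhood size for a core point (>= 2).
#' @param eps neighborhood radius; `Inf` disables the radius cutoff.
#' @return An object of class `optics_result` with fields `ordering`
#'   (item IDs in processing order), `reachability` (first item `Inf`;
#'   finite values never exceed `eps`), `core_distance`, and `params`.
#' @export
run_optics <- function(m, min_pts = 5L, eps = Inf) {
  stopifnot(inherits(m, "expr_matrix"))
  n <- nrow(m$values)
  if (min_pts < 2L) stop("min_pts must be >= 2", call. = FALSE)
  if (min_pts > n)
    stop("min_pts = ", min_pts, " exceeds the number of items (", n, ")",
         call. = FALSE)
  d <- as.matrix(stats::dist(m$values))
  core <- rep(Inf, n)
  for (i in seq_len(n)) {
    nb <- sort(d[i, d[i, ] <= eps])       # includes self at distance 0
    if (length(nb) >= min_pts) core[i] <- nb[min_pts]
  }
  processed <- logical(n)
  inseeds <- logical(n)
  seedval <- rep(Inf, n)
  order_idx <- integer(n)
  reach <- rep(Inf, n)                    # recorded in output order
  pos <- 0L

  emit <- function(i, r) {
    pos <<- pos + 1L
    order_idx[pos] <<- i
    reach[pos] <<- r
    processed[i] <<- TRUE
    inseeds[i] <<- FALSE
  }
  update_seeds <- function(i) {
    if (!is.finite(core[i])) return(invisible())
    nbr <- which(d[i, ] <= eps & !processed)
    newreach <- pmax(core[i], d[i, nbr])
    seedval[nbr] <<- pmin(seedval[nbr], newreach)
    inseeds[nbr] <<- TRUE
    invisible()
  }
  for (start in seq_len(n)) {
    if (processed[start]) next
    emit(start, Inf)
    update_seeds(start)
    while (any(inseeds)) {
      cand <- which(inseeds)
      q <- cand[which.min(seedval[cand])]   # ties: smallest index
      r <- seedval[q]
      seedval[q] <- Inf
      emit(q, r)
      update_seeds(q)
    }
  }
  ids <- item_ids(m)
  structure(list(ordering = ids[order_idx],
                 reachability = reach,
                 core_distance = stats::setNames(core, ids),
                 params = list(min_pts = as.integer(min_pts), eps = eps)),
            class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("<optics_result> %d items, min_pts=%d, eps=%s\n",
              length(x$ordering), x$params$min_pts,
              format(x$params$eps)))
  invisible(x)
}

#' Extract clusters from an OPTICS reachability plot
#'
#' Horizontal-cut extraction: scanning the ordering, maximal runs of
#' consecutive items with reachability at most `r_threshold` — together
#' with the immediately preceding item, which opened the valley — form
#' candidate clusters; candidates with at least `min_pts` members become
#' clusters and everything else joins a single noise cluster. The start
#' and end positions of each cluster in the ordering are retained (in
#' `$extra$spans`) so the reachability renderer can draw its horizontal
#' cluster bars.
#'
#' @param o an `optics_result`.
#' @param r_threshold positive reachability cut.
#' @param min_pts minimum cluster size; defaults to the OPTICS `min_pts`.
#' @param result_id identifier for the derived result.
#' @return A [clustering_result()] with `algorithm = "optics"`; the noise
#'   cluster (label `"(noise)"`) is present when any item is unassigned.
#' @export
extract_optics_clusters <- function(o, r_threshold,
                                    min_pts = o$params$min_pts,
                                    result_id = sprintf(
                                      "OPTICS(min_pts=%d,r=%g)",
                                      o$params$min_pts, r_threshold)) {
  stopifnot(inherits(o, "optics_result"))
  if (r_threshold <= 0) stop("r_threshold must be > 0", call. = FALSE)
  n <- length(o$ordering)
  low <- o$reachability <= r_threshold
  lab <- rep(NA_character_, n)
  spans <- list()
  i <- 1L; cl <- 0L
  while (i <= n) {
    if (low[i]) {
      j <- i
      while (j < n && low[j + 1L]) j <- j + 1L
      start <- max(1L, i - 1L)           # valley-opening item joins the run
      if (j - start + 1L >= min_pts) {
        cl <- cl + 1L
        label <- sprintf("C%d", cl)
        lab[start:j] <- label
        spans[[label]] <- c(start = start, end = j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  noise <- is.na(lab)
  lab[noise] <- "(noise)"
  assignment <- stats::setNames(lab, o$ordering)
  clustering_result(result_id, "optics",
                    params = list(min_pts = o$params$min_pts,
                                  eps = o$params$eps,
                                  r_threshold = r_threshold),
                    assignment = assignment,
                    noise_label = if (any(noise)) "(noise)" else NULL,
                    extra = list(spans = spans))
}
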