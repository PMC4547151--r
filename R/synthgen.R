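#' Planted-cluster expression matrix
#'
#' Generates a synthetic items-by-conditions matrix emulating the shape
#' of normalized expression datasets (a few hundred to a few thousand
#' rows, a handful to ~19 condition columns): `k` Gaussian cluster
#' profiles around centroids placed on an axis-aligned simplex scaled so
#' any two centroids are at least `separation * noise_sd` apart, plus an
#' optional fraction of unstructured scatter rows labelled as the planted
#' noise cluster (exercising the un-clustered-items-as-one-cluster
#' policy end to end). Regeneration with identical parameters is
#' bit-identical.
#'
#' @param n_items total rows (>= k).
#' @param n_conditions columns; must be >= k so the centroid simplex fits.
#' @param k number of planted clusters (>= 1).
#' @param separation centroid spacing in units of `noise_sd`.
#' @param noise_sd standard deviation of the per-entry Gaussian noise.
#' @param noise_fraction fraction of rows drawn uniformly over the data
#'   range and labelled noise in the truth.
#' @param seed integer RNG seed.
#' @return A list of class `planted_dataset`: `matrix` (an
#'   [expression_matrix()]), `truth` (a [clustering_result()] with the
#'   planted labels `G1..Gk` and noise label `"(noise)"`), and `params`.
#' @export
planted_matrix <- function(n_items, n_conditions, k, separation = 8,
                           noise_sd = 1, noise_fraction = 0, seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n_items < k) stop("n_items must be >= k", call. = FALSE)
  if (separation < 0 || noise_sd < 0)
    stop("separation and noise_sd must be >= 0", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)", call. = FALSE)
  if (k > n_conditions)
    stop("cannot place ", k, " centroids in ", n_conditions,
         " conditions; need n_conditions >= k", call. = FALSE)
  set.seed(seed)
  spacing <- separation * noise_sd
  # axis-aligned simplex: centroid j sits at spacing on axis j, so any two
  # centroids are spacing * sqrt(2) >= spacing apart
  centroids <- matrix(0, k, n_conditions)
  for (j in seq_len(k)) centroids[j, j] <- spacing

  n_noise <- floor(noise_fraction * n_items)
  n_clustered <- n_items - n_noise
  base <- n_clustered %/% k
  sizes <- rep(base, k) + c(rep(1L, n_clustered - base * k),
                            rep(0L, k - (n_clustered - base * k)))
  labels <- rep(sprintf("G%d", seq_len(k)), times = sizes)
  x <- centroids[rep(seq_len(k), times = sizes), , drop = FALSE] +
    matrix(stats::rnorm(n_clustered * n_conditions, sd = noise_sd),
           n_clustered, n_conditions)
  if (n_noise > 0L) {
    lo <- min(x, 0); hi <- max(x, spacing)
    nz <- matrix(stats::runif(n_noise * n_conditions, lo, hi),
                 n_noise, n_conditions)
    x <- rbind(x, nz)
    labels <- c(labels, rep("(noise)", n_noise))
  }
  ids <- sprintf("item%04d", seq_len(n_items))
  rownames(x) <- ids
  colnames(x) <- sprintf("cond%02d", seq_len(n_conditions))
  m <- expression_matrix(x, provenance = sprintf(
    "planted_matrix(n=%d, p=%d, k=%d, sep=%g, sd=%g, noise=%g, seed=%d)",
    n_items, n_conditions, k, separation, noise_sd, noise_fraction, seed))
  truth <- clustering_result(
    sprintf("planted(k=%d,seed=%d)", k, seed), "planted",
    params = list(n_items = n_items, n_conditions = n_conditions, k = k,
                  separation = separation, noise_sd = noise_sd,
                  noise_fraction = noise_fraction, seed = seed),
    assignment = stats::setNames(labels, ids),
    noise_label = if (n_noise > 0L) "(noise)" else NULL)
  structure(list(matrix = m, truth = truth, params = truth$params),
            class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat(sprintf("<planted_dataset> %d x %d, k=%d, separation=%g\n",
              x$params$n_items, x$params$n_conditions, x$params$k,
              x$params$separation))
  invisible(x)
}

#' Randomly perturb a partition
#'
#' Reassigns exactly `floor(flip_fraction * n)` uniformly chosen items to
#' uniformly chosen *other* clusters, producing families of near-
#' duplicate results like repeated k-means runs. Deterministic for a
#' fixed seed. Clusters emptied by the move are dropped.
#'
#' @param r a `clustering_result` (>= 2 clusters when `flip_fraction > 0`).
#' @param flip_fraction fraction of items to move, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param result_id identifier for the perturbed result.
#' @return A [clustering_result()].
#' @export
perturb_partition <- function(r, flip_fraction, seed = 1L,
                              result_id = sprintf("%s~flip%g",
                                                  r$result_id,
                                                  flip_fraction)) {
  stopifnot(inherits(r, "clustering_result"),
            flip_fraction >= 0, flip_fraction <= 1)
  labels <- names(r$clusters)
  if (flip_fraction > 0 && length(labels) < 2L)
    stop("cannot flip items in a single-cluster partition", call. = FALSE)
  assignment <- r$assignment
  n <- length(assignment)
  nflip <- floor(flip_fraction * n)
  set.seed(seed)
  if (nflip > 0L) {
    idx <- sample.int(n, nflip)
    for (i in idx) {
      others <- setdiff(labels, assignment[[i]])
      assignment[i] <- others[sample.int(length(others), 1L)]
    }
  }
  noise <- r$noise_label
  if (!is.na(noise) && !noise %in% assignment) noise <- NA_character_
  clustering_result(result_id, r$algorithm,
                    params = c(r$params,
                               list(flip_fraction = flip_fraction,
                                    flip_seed = seed)),
                    assignment = assignment,
                    noise_label = if (is.na(noise)) NULL else noise)
}
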