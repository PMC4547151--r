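#' Self-organizing map on a hexagonal grid
#'
#' Classic online SOM with hexagonal topology (odd rows offset by half a
#' cell), Gaussian neighborhood, and radius and learning rate decaying
#' linearly over epochs. Codebook vectors are initialized by greedy
#' farthest-point sampling of data rows under the given seed, so training
#' is fully reproducible. Empty cells are carried in the grid (size 0)
#' but excluded from the partition view, where each non-empty cell is one
#' cluster.
#'
#' @param m an `expr_matrix`.
#' @param rows,cols grid dimensions; `rows * cols >= 1`. A grid larger
#'   than the item count is allowed and simply leaves cells empty.
#' @param epochs training passes over the data (>= 1).
#' @param seed integer RNG seed.
#' @param alpha learning rate, decayed linearly from `alpha[1]` to
#'   `alpha[2]`.
#' @param result_id identifier for the partition view.
#' @return An object of class `som_result`: grid geometry, codebook,
#'   item-to-cell mapping, and `$clustering` — the
#'   [clustering_result()] view over non-empty cells (labels
#'   `cell_<row>_<col>`).
#' @export
run_som <- function(m, rows, cols, epochs = 30L, seed = 1L,
                    alpha = c(0.3, 0.01),
                    result_id = sprintf("SOM(%dx%d,seed=%d)",
                                        rows, cols, seed)) {
  stopifnot(inherits(m, "expr_matrix"))
  if (rows < 1L || cols < 1L) stop("grid must be at least 1x1",
                                   call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  x <- m$values
  n <- nrow(x)
  ncell <- rows * cols
  # hexagonal cell centers: odd rows shifted right by half a cell
  cell_row <- rep(seq_len(rows), each = cols)
  cell_col <- rep(seq_len(cols), times = rows)
  gx <- cell_col + 0.5 * ((cell_row - 1L) %% 2L)
  gy <- (cell_row - 1L) * sqrt(3) / 2
  grid_d2 <- as.matrix(stats::dist(cbind(gx, gy)))^2

  set.seed(seed)
  if (ncell <= n) {
    w <- seed_centers(x, ncell)
  } else {
    w <- x[c(seq_len(n), sample.int(n, ncell - n, replace = TRUE)), ,
           drop = FALSE]
  }
  rownames(w) <- NULL

  r0 <- max(rows, cols) / 2; r1 <- 0.2
  for (e in seq_len(epochs)) {
    t <- if (epochs > 1L) (e - 1L) / (epochs - 1L) else 0
    radius <- r0 + (r1 - r0) * t
    lr <- alpha[1L] + (alpha[2L] - alpha[1L]) * t
    for (i in sample.int(n)) {
      xi <- x[i, ]
      d2 <- rowSums(sweep(w, 2L, xi)^2)
      bmu <- which.min(d2)
      infl <- lr * exp(-grid_d2[bmu, ] / (2 * radius^2))
      w <- w + infl * sweep(-w, 2L, xi, `+`)
    }
  }
  d2 <- outer(rowSums(x^2), rowSums(w^2), `+`) - 2 * x %*% t(w)
  cell_of <- max.col(-d2, ties.method = "first")
  labels <- sprintf("cell_%d_%d", cell_row, cell_col)
  assignment <- stats::setNames(labels[cell_of], item_ids(m))
  cr <- clustering_result(result_id, "som",
                          params = list(rows = rows, cols = cols,
                                        epochs = epochs, seed = seed),
                          assignment = assignment)
  structure(list(rows = rows, cols = cols,
                 cell_row = cell_row, cell_col = cell_col,
                 cell_x = gx, cell_y = gy,
                 codebook = w,
                 cell_labels = labels,
                 cell_of = stats::setNames(cell_of, item_ids(m)),
                 clustering = cr,
                 params = cr$params),
            class = "som_result")
}

#' @export
print.som_result <- function(x, ...) {
  cat(sprintf("<som_result> %dx%d grid, %d non-empty cells, %d items\n",
              x$rows, x$cols, length(x$clustering$clusters),
              length(x$cell_of)))
  invisible(x)
}
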