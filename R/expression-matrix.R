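#' Expression matrix container
#'
#' An `expr_matrix` holds an items-by-conditions numeric matrix (genes in
#' rows, conditions in columns) together with a provenance log of the
#' derivations and filters that produced it. Values carry whatever unit the
#' source file used (RPKM, log-ratio, ...).
#'
#' @param values numeric matrix with unique row names (item IDs) and unique
#'   column names (condition IDs); all entries must be finite.
#' @param provenance character vector describing the operations applied so
#'   far, oldest first.
#' @param derived character vector of column names created by
#'   [derive_column()]; these are excluded from RPKM-style thresholding,
#'   which operates on the original measurement columns.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, provenance = character(),
                              derived = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix must have at least one row and one column",
         call. = FALSE)
  ids <- rownames(values)
  conds <- colnames(values)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all rows must carry a non-empty item ID", call. = FALSE)
  if (is.null(conds) || anyNA(conds) || any(conds == ""))
    stop("all columns must carry a non-empty condition ID", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate item ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  if (anyDuplicated(conds))
    stop("duplicate condition ID: ", conds[duplicated(conds)][1L],
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  structure(list(values = values,
                 provenance = as.character(provenance),
                 derived = as.character(derived)),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Item and condition identifiers
#'
#' @param m an `expr_matrix`.
#' @return Character vector of row (item) or column (condition) IDs.
#' @export
item_ids <- function(m) rownames(m$values)

#' @rdname item_ids
#' @export
condition_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d items x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$provenance))
    cat("provenance:\n", paste0("  - ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Read an expression matrix from CSV or tab-delimited text
#'
#' The first row is a header, the first column holds item IDs. With
#' `delimiter = "auto"` the file is read as tab-delimited when the header
#' line contains a tab character, otherwise as comma-separated.
#'
#' @param path path to the text file.
#' @param delimiter `"auto"`, `"comma"` or `"tab"`.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, delimiter = c("auto", "comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(header))
    stop("empty file: ", path, call. = FALSE)
  sep <- switch(delimiter,
                comma = ",",
                tab = "\t",
                auto = if (grepl("\t", header, fixed = TRUE)) "\t" else ",")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("need an ID column plus at least one condition column", call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate item ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  conds <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(conds),
                 dimnames = list(ids, conds))
  for (j in seq_along(conds)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      stop(sprintf("non-numeric value %s in row %d (item %s), column %s",
                   dQuote(col[bad[1L]]), bad[1L], ids[bad[1L]], conds[j]),
           call. = FALSE)
    vals[, j] <- num
  }
  expression_matrix(vals, provenance = sprintf("read_matrix(%s)",
                                               basename(path)))
}

#' Derive a ratio or log2 fold-change column
#'
#' Appends a column computed from two existing condition columns:
#' `ratio = (a + c) / (b + c)` or `log2fc = log2((a + c) / (b + c))`, where
#' `c` is a pseudocount that keeps zero denominators finite (standard
#' RNA-seq practice; default 1).
#'
#' @param m an `expr_matrix`.
#' @param kind `"ratio"` or `"log2fc"`.
#' @param numerator,denominator existing condition IDs.
#' @param pseudocount non-negative offset added to both columns; must be
#'   positive when any denominator entry is zero, or when `kind = "log2fc"`
#'   and any shifted ratio would be non-positive.
#' @return A new `expr_matrix` with the extra column; existing columns are
#'   untouched and the derivation is recorded in provenance.
#' @export
derive_column <- function(m, kind = c("ratio", "log2fc"),
                          numerator, denominator, pseudocount = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(m, "expr_matrix"))
  conds <- condition_ids(m)
  for (col in c(numerator, denominator))
    if (!col %in% conds) stop("unknown column: ", col, call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  a <- m$values[, numerator] + pseudocount
  b <- m$values[, denominator] + pseudocount
  if (any(b == 0))
    stop("zero denominator in column ", denominator,
         " with pseudocount 0; use a positive pseudocount", call. = FALSE)
  ratio <- a / b
  if (kind == "log2fc" && any(ratio <= 0))
    stop("non-positive ratio; log2 fold change undefined", call. = FALSE)
  newcol <- if (kind == "ratio") ratio else log2(ratio)
  name <- if (kind == "ratio") sprintf("%s/%s", numerator, denominator)
          else sprintf("log2FC(%s/%s)", numerator, denominator)
  if (name %in% conds) stop("column already exists: ", name, call. = FALSE)
  vals <- cbind(m$values, newcol)
  colnames(vals)[ncol(vals)] <- name
  expression_matrix(vals,
                    provenance = c(m$provenance,
                                   sprintf("derive_column(%s, %s, %s, c=%g)",
                                           kind, numerator, denominator,
                                           pseudocount)),
                    derived = c(m$derived, name))
}

#' Row filters for expression matrices
#'
#' `range_filter()` keeps rows whose value in one column lies in the closed
#' interval `[lo, hi]`. `rpkm_filter()` keeps rows whose expression over the
#' original (non-derived) condition columns reaches `threshold`: with
#' `scope = "max"` at least one column must reach it, with `scope = "all"`
#' every column must.
#'
#' @param column a condition ID.
#' @param lo,hi closed interval bounds.
#' @param threshold non-negative abundance cutoff (e.g. in RPKM).
#' @param scope `"max"` or `"all"`.
#' @return A filter rule object for [filter_rows()].
#' @export
range_filter <- function(column, lo, hi) {
  stopifnot(is.character(column), length(column) == 1L, lo <= hi)
  structure(list(column = column, lo = lo, hi = hi), class = "range_filter")
}

#' @rdname range_filter
#' @export
rpkm_filter <- function(threshold, scope = c("max", "all")) {
  scope <- match.arg(scope)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, scope = scope),
            class = "rpkm_filter")
}

#' Filter matrix rows by a rule
#'
#' Row order is preserved; the applied rule is recorded in provenance.
#' A filter that would remove every row is an error, because an empty
#' matrix cannot be clustered downstream.
#'
#' @param m an `expr_matrix`.
#' @param rule a [range_filter()] or [rpkm_filter()] rule.
#' @return The filtered `expr_matrix`.
#' @export
filter_rows <- function(m, rule) {
  stopifnot(inherits(m, "expr_matrix"))
  if (inherits(rule, "range_filter")) {
    if (!rule$column %in% condition_ids(m))
      stop("unknown column: ", rule$column, call. = FALSE)
    v <- m$values[, rule$column]
    keep <- v >= rule$lo & v <= rule$hi
    tag <- sprintf("range(%s, %g, %g)", rule$column, rule$lo, rule$hi)
  } else if (inherits(rule, "rpkm_filter")) {
    orig <- setdiff(condition_ids(m), m$derived)
    sub <- m$values[, orig, drop = FALSE]
    keep <- if (rule$scope == "max")
      apply(sub, 1L, max) >= rule$threshold
    else
      apply(sub, 1L, min) >= rule$threshold
    tag <- sprintf("rpkm_threshold(%g, %s)", rule$threshold, rule$scope)
  } else stop("unknown filter rule", call. = FALSE)
  if (!any(keep))
    stop("filter removes all rows: ", tag, call. = FALSE)
  expression_matrix(m$values[keep, , drop = FALSE],
                    provenance = c(m$provenance, tag),
                    derived = m$derived)
}

#' Export a subset of items as CSV
#'
#' Writes the selected items (in matrix row order) with all condition
#' columns so the file round-trips through [read_matrix()].
#'
#' @param items character vector of item IDs; must be a non-empty subset of
#'   the matrix items.
#' @param m an `expr_matrix`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_group <- function(items, m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(items) == 0L) stop("cannot export an empty item set",
                                call. = FALSE)
  missing <- setdiff(items, item_ids(m))
  if (length(missing))
    stop("items not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- item_ids(m) %in% items
  sub <- m$values[keep, , drop = FALSE]
  df <- data.frame(item = rownames(sub),
                   format(sub, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
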