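#' Annotated numeric matrix with unique row/column identifiers
#'
#' The basic container shared by perturbation z-score profiles, cohort
#' expression matrices and dependency-score tables: a genes-by-samples numeric
#' matrix with unique row and column identifiers and optional per-identifier
#' metadata (e.g. cell line and timepoint for perturbation columns).
#'
#' @param values Numeric matrix. Dimnames, if present, are used as identifiers
#'   unless `row_ids`/`col_ids` are given.
#' @param row_ids,col_ids Character vectors of unique identifiers; defaults to
#'   the matrix dimnames.
#' @param row_meta,col_meta Optional data frames of per-identifier annotation,
#'   one row per id in the same order.
#' @return An object of class `matrix_table`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' mt <- matrix_table(m)
#' dim(mt)
#' @export
matrix_table <- function(values, row_ids = rownames(values), col_ids = colnames(values),
                         row_meta = NULL, col_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("values must be a numeric matrix")
  }
  if (is.null(row_ids) || is.null(col_ids)) {
    abort_validation("row and column identifiers are required (dimnames or explicit ids)")
  }
  row_ids <- trimws(as.character(row_ids))
  col_ids <- trimws(as.character(col_ids))
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    abort_validation("id lengths (%d, %d) do not match matrix dimensions (%d, %d)",
                     length(row_ids), length(col_ids), nrow(values), ncol(values))
  }
  dup_r <- unique(row_ids[duplicated(row_ids)])
  if (length(dup_r)) {
    abort_validation("duplicate row ids: %s", paste(dup_r, collapse = ", "))
  }
  dup_c <- unique(col_ids[duplicated(col_ids)])
  if (length(dup_c)) {
    abort_validation("duplicate column ids: %s", paste(dup_c, collapse = ", "))
  }
  if (any(is.infinite(values))) {
    abort_validation("matrix values must be finite or NA")
  }
  for (meta in list(row_meta, col_meta)) {
    if (!is.null(meta) && !is.data.frame(meta)) {
      abort_validation("row_meta/col_meta must be data frames or NULL")
    }
  }
  if (!is.null(row_meta) && nrow(row_meta) != length(row_ids)) {
    abort_validation("row_meta has %d rows for %d row ids", nrow(row_meta), length(row_ids))
  }
  if (!is.null(col_meta) && nrow(col_meta) != length(col_ids)) {
    abort_validation("col_meta has %d rows for %d column ids", nrow(col_meta), length(col_ids))
  }
  dimnames(values) <- list(row_ids, col_ids)
  structure(
    list(values = values, row_meta = row_meta, col_meta = col_meta),
    class = "matrix_table"
  )
}

#' @export
dim.matrix_table <- function(x) dim(x$values)

#' @export
dimnames.matrix_table <- function(x) dimnames(x$values)

#' Row and column identifiers of a matrix_table
#' @param x A `matrix_table`.
#' @return Character vector of identifiers.
#' @export
row_ids <- function(x) rownames(x$values)

#' @rdname row_ids
#' @export
col_ids <- function(x) colnames(x$values)

#' @export
print.matrix_table <- function(x, ...) {
  cat(sprintf("<matrix_table> %d rows x %d cols\n", nrow(x$values), ncol(x$values)))
  if (!is.null(x$col_meta)) {
    cat("  col_meta:", paste(names(x$col_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
all.equal.matrix_table <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}
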