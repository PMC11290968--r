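#' Read a GCT 1.2 expression matrix
#'
#' Parses the tab-separated GCT 1.2 text dialect used across the LINCS /
#' connectivity-map ecosystem: a `#1.2` version line, a `nrows<TAB>ncols`
#' dimensions line, a header row (`Name`, `Description`, sample ids), then one
#' row per gene. `NA` or empty cells are read as missing.
#'
#' @param path Path to a GCT file.
#' @return A [matrix_table] whose `row_meta` carries the `Description` column.
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort_format("GCT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort_format("GCT file too short (%d lines): %s", length(lines), path)
  if (trimws(lines[[1L]]) != "#1.2") {
    abort_format("malformed GCT header line 1 (expected \"#1.2\"): %s", lines[[1L]])
  }
  dims <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  ndim <- suppressWarnings(as.integer(dims))
  if (length(ndim) < 2L || anyNA(ndim[1:2]) || any(ndim[1:2] < 1L)) {
    abort_format("malformed GCT dimensions line 2: %s", lines[[2L]])
  }
  n_rows <- ndim[[1L]]; n_cols <- ndim[[2L]]
  header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != n_cols + 2L) {
    abort_format("GCT header declares %d data columns but dimensions line says %d",
                 length(header) - 2L, n_cols)
  }
  if (length(lines) < 3L + n_rows) {
    abort_format("GCT declares %d rows but file has only %d data lines",
                 n_rows, length(lines) - 3L)
  }
  body <- lines[seq(4L, 3L + n_rows)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != n_cols + 2L)
  if (length(bad)) {
    abort_format("GCT data line %d has %d fields, expected %d",
                 bad[[1L]] + 3L, length(fields[[bad[[1L]]]]), n_cols + 2L)
  }
  ids  <- trimws(vapply(fields, `[[`, "", 1L))
  desc <- vapply(fields, `[[`, "", 2L)
  vals <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    cells <- fields[[i]][-(1:2)]
    cells[cells == "" | cells == "NA"] <- NA
    vals[i, ] <- suppressWarnings(as.numeric(cells))
    bad_cell <- which(is.na(vals[i, ]) & !(is.na(cells)))
    if (length(bad_cell)) {
      abort_format("non-numeric cell %s at data line %d", cells[[bad_cell[[1L]]]], i + 3L)
    }
  }
  matrix_table(vals, row_ids = ids, col_ids = trimws(header[-(1:2)]),
               row_meta = data.frame(description = desc, stringsAsFactors = FALSE))
}

#' Write a matrix_table as GCT 1.2
#'
#' Inverse of [read_gct()]: `read_gct(write_gct(x, p))` reproduces the data
#' block. Values are written with full `%.17g` precision so round-trips are
#' numerically exact. Identifiers containing tabs or newlines are rejected
#' (they would corrupt the format).
#'
#' @param table A [matrix_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(table, path) {
  stopifnot(inherits(table, "matrix_table"))
  ids <- c(row_ids(table), col_ids(table))
  if (any(grepl("[\t\n\r]", ids))) {
    abort_validation("ids must not contain tab or newline characters")
  }
  desc <- table$row_meta$description %||% rep("", nrow(table$values))
  vals <- table$values
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(row_ids(table)[i], desc[i], fmt(vals[i, ])), collapse = "\t")
  }, "")
  lines <- c(
    "#1.2",
    paste(nrow(vals), ncol(vals), sep = "\t"),
    paste(c("Name", "Description", col_ids(table)), collapse = "\t"),
    body
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort("cannot open %s for writing: %s", "sigdiscord_io_error", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
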