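#' Labeled tumor expression cohort
#'
#' Bundles a genes-by-patients expression matrix with per-patient molecular
#' subgroup labels and optional overall-survival data, plus a declared
#' expression scale (`"log2"` for microarray-style data, `"linear"` for
#' nonnegative intensities).
#'
#' @param expr A [matrix_table], genes x patients.
#' @param subgroup Named character vector mapping every patient id to a
#'   subgroup label (e.g. WNT, SHH, G3, G4).
#' @param survival Optional data frame with columns `sample_id`, `os_time`
#'   (days, > 0) and `os_event` (0 = censored, 1 = event).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(expr, subgroup, survival = NULL, scale = c("log2", "linear")) {
  stopifnot(inherits(expr, "matrix_table"))
  scale <- match.arg(scale)
  patients <- col_ids(expr)
  if (is.null(names(subgroup))) abort_validation("subgroup must be a named vector")
  missing_lab <- setdiff(patients, names(subgroup))
  if (length(missing_lab)) {
    abort_validation("%d patients lack a subgroup label (first: %s)",
                     length(missing_lab), missing_lab[[1L]])
  }
  subgroup <- as.character(subgroup[patients])
  names(subgroup) <- patients
  if (!is.null(survival)) {
    req <- c("sample_id", "os_time", "os_event")
    if (!all(req %in% names(survival))) {
      abort_validation("survival needs columns %s", paste(req, collapse = ", "))
    }
    survival <- survival[survival$sample_id %in% patients, req, drop = FALSE]
    if (!all(survival$os_event %in% c(0, 1))) {
      abort_validation("os_event must be 0 or 1")
    }
    if (any(!is.finite(survival$os_time)) || any(survival$os_time <= 0)) {
      abort_validation("os_time must be finite and > 0")
    }
    rownames(survival) <- NULL
  }
  structure(
    list(expr = expr, subgroup = subgroup, survival = survival, scale = scale),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %d genes x %d patients (%s scale)\n",
              nrow(x$expr$values), ncol(x$expr$values), x$scale))
  print(table(x$subgroup))
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: %d patients, %d events\n",
                nrow(x$survival), sum(x$survival$os_event)))
  }
  invisible(x)
}

#' Read an expression cohort from disk
#'
#' Expression is read from GCT (detected by a `#1.2` first line) or from a
#' plain TSV with gene ids in the first column. Metadata is a TSV with columns
#' `sample_id`, `subgroup` and optionally `os_time`, `os_event`. Patients
#' present in both files are retained; patients missing from the metadata are
#' dropped with a warning giving the count.
#'
#' @param expr_path Path to the expression matrix (GCT or TSV).
#' @param meta_path Path to the metadata TSV.
#' @param scale Declared expression scale, `"log2"` (default) or `"linear"`.
#' @return An [expression_cohort].
#' @export
read_cohort <- function(expr_path, meta_path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  first <- readLines(expr_path, n = 1L, warn = FALSE)
  if (identical(trimws(first), "#1.2")) {
    expr <- read_gct(expr_path)
  } else {
    df <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    expr <- matrix_table(vals, row_ids = df[[1L]], col_ids = colnames(df)[-1L])
  }
  meta <- utils::read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subgroup") %in% names(meta))) {
    abort_validation("metadata must have sample_id and subgroup columns")
  }
  meta$sample_id <- trimws(as.character(meta$sample_id))
  keep <- intersect(col_ids(expr), meta$sample_id)
  if (length(keep) == 0L) {
    abort_validation("no overlapping patients between expression (%d) and metadata (%d)",
                     ncol(expr$values), nrow(meta))
  }
  dropped <- setdiff(col_ids(expr), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d patients absent from metadata", length(dropped)),
            call. = FALSE)
  }
  expr <- matrix_table(expr$values[, keep, drop = FALSE], row_meta = expr$row_meta)
  meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  subgroup <- stats::setNames(as.character(meta$subgroup), meta$sample_id)
  surv <- NULL
  if (all(c("os_time", "os_event") %in% names(meta))) {
    surv <- data.frame(sample_id = meta$sample_id,
                       os_time = as.numeric(meta$os_time),
                       os_event = as.numeric(meta$os_event),
                       stringsAsFactors = FALSE)
    surv <- surv[!is.na(surv$os_time) & !is.na(surv$os_event), , drop = FALSE]
  }
  expression_cohort(expr, subgroup, survival = surv, scale = scale)
}

#' Subgroup levels present in a cohort
#' @param cohort An [expression_cohort].
#' @return Sorted character vector of subgroup labels.
#' @export
subgroup_levels <- function(cohort) sort(unique(cohort$subgroup))
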