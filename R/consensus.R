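#' Drug transcriptional consensus response signature
#'
#' Per-gene summary of a drug's effect across cell lines: the mean
#' differential z-score over *all* cell lines (`consensus_z`), the direction
#' in which the gene met the retention rule (`direction`), and the fraction
#' of cell lines supporting that direction (`agreement`). Genes are retained
#' only if they changed in the same direction (|z| >= `z_min`) in at least a
#' fraction `tau` of the cell lines, in exactly one direction.
#'
#' @param entries Data frame with columns `gene`, `consensus_z`, `direction`
#'   (`"up"`/`"down"`), `agreement`.
#' @param params List recording `tau`, `z_min` and the `timepoint` used.
#' @return An object of class `consensus_signature`.
#' @export
consensus_signature <- function(entries, params) {
  req <- c("gene", "consensus_z", "direction", "agreement")
  stopifnot(is.data.frame(entries), all(req %in% names(entries)))
  if (anyDuplicated(entries$gene)) abort_validation("duplicate genes in signature")
  if (!all(entries$direction %in% c("up", "down"))) {
    abort_validation("direction must be \"up\" or \"down\"")
  }
  rownames(entries) <- NULL
  structure(list(entries = entries[, req], params = params),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("<consensus_signature> %d genes (%d up, %d down), tau=%.2f, z_min=%.2f\n",
              nrow(x$entries), sum(x$entries$direction == "up"),
              sum(x$entries$direction == "down"),
              x$params$tau %||% NA, x$params$z_min %||% NA))
  invisible(x)
}

#' @export
length.consensus_signature <- function(x) nrow(x$entries)

#' Genes contained in a consensus signature
#' @param sig A [consensus_signature].
#' @return Character vector of gene ids.
#' @export
signature_genes <- function(sig) sig$entries$gene

#' Restrict a profile set to one timepoint and average replicates per cell line
#'
#' Columns are filtered to the requested timepoint, then averaged within each
#' cell line so the result has exactly one column per cell line (column ids
#' become the cell-line ids).
#'
#' @param profiles A [matrix_table] whose `col_meta` has `cell_line` and
#'   `timepoint` columns.
#' @param timepoint Timepoint label to keep, e.g. `"24 h"`.
#' @return A [matrix_table], genes x cell lines.
#' @export
collapse_cell_lines <- function(profiles, timepoint = "24 h") {
  stopifnot(inherits(profiles, "matrix_table"))
  meta <- profiles$col_meta
  if (is.null(meta) || !all(c("cell_line", "timepoint") %in% names(meta))) {
    abort_validation("profiles col_meta must carry cell_line and timepoint")
  }
  keep <- which(meta$timepoint == timepoint)
  if (length(keep) == 0L) {
    abort_validation("no columns at timepoint \"%s\"", timepoint)
  }
  vals <- profiles$values[, keep, drop = FALSE]
  lines <- meta$cell_line[keep]
  uniq <- unique(lines)
  out <- vapply(uniq, function(cl) {
    rowMeans(vals[, lines == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals), dimnames = list(rownames(vals), uniq))
  out[is.nan(out)] <- NA
  matrix_table(out)
}

#' Build a consensus response signature from per-cell-line z-scores
#'
#' A gene is retained iff the fraction of cell lines with `z >= z_min`
#' reaches `tau`, or the fraction with `z <= -z_min` does — but not both
#' (direction-conflicted genes are excluded). The consensus value is the
#' mean z over all cell lines, responders and non-responders alike. Missing
#' values are handled available-case: fractions use the number of observed
#' lines for that gene, and the mean skips them.
#'
#' @param profiles_by_line A [matrix_table] with one column per cell line
#'   (output of [collapse_cell_lines()]).
#' @param tau Retention fraction in (0, 1]; default 0.30.
#' @param z_min Per-line change threshold in z-score units (> 0); default 2,
#'   roughly two-sided 0.05 on a standard-normal score.
#' @param timepoint Label recorded in the signature's params.
#' @return A [consensus_signature].
#' @export
build_consensus <- function(profiles_by_line, tau = 0.30, z_min = 2.0,
                            timepoint = "24 h") {
  stopifnot(inherits(profiles_by_line, "matrix_table"))
  if (tau <= 0 || tau > 1) abort_validation("tau must be in (0, 1]")
  if (z_min <= 0) abort_validation("z_min must be > 0")
  z <- profiles_by_line$values
  if (ncol(z) < 2L) abort_validation("need >= 2 cell lines, got %d", ncol(z))
  n_obs <- rowSums(!is.na(z))
  frac_up <- rowSums(z >= z_min, na.rm = TRUE) / n_obs
  frac_down <- rowSums(z <= -z_min, na.rm = TRUE) / n_obs
  up_ok <- n_obs > 0 & frac_up >= tau
  down_ok <- n_obs > 0 & frac_down >= tau
  keep <- xor(up_ok, down_ok)
  entries <- data.frame(
    gene = rownames(z)[keep],
    consensus_z = rowMeans(z, na.rm = TRUE)[keep],
    direction = ifelse(up_ok[keep], "up", "down"),
    agreement = ifelse(up_ok[keep], frac_up[keep], frac_down[keep]),
    stringsAsFactors = FALSE
  )
  consensus_signature(entries,
                      params = list(tau = tau, z_min = z_min, timepoint = timepoint))
}

#' Keep the top-k genes of a signature by absolute consensus z
#'
#' Optionally restricts to a gene universe first (e.g. genes present in a
#' disease cohort), then ranks by decreasing |consensus_z| with ties broken
#' lexicographically by gene id, keeping the first `k`.
#'
#' @param sig A [consensus_signature].
#' @param k Number of genes to keep (>= 1).
#' @param universe Optional character vector restricting eligible genes.
#' @return A [consensus_signature].
#' @export
top_genes <- function(sig, k, universe = NULL) {
  stopifnot(inherits(sig, "consensus_signature"))
  if (!is_count(k)) abort_validation("k must be a positive integer")
  e <- sig$entries
  if (!is.null(universe)) e <- e[e$gene %in% universe, , drop = FALSE]
  ord <- order(-abs(e$consensus_z), e$gene)
  e <- e[ord[seq_len(min(k, nrow(e)))], , drop = FALSE]
  consensus_signature(e, sig$params)
}

#' Partition a signature into up- and downregulated gene lists
#'
#' @param sig A [consensus_signature].
#' @return List with character vectors `up` and `down`.
#' @export
split_directions <- function(sig) {
  stopifnot(inherits(sig, "consensus_signature"))
  list(up = sig$entries$gene[sig$entries$direction == "up"],
       down = sig$entries$gene[sig$entries$direction == "down"])
}

#' Write / read a consensus signature as TSV
#'
#' Columns: gene, consensus_z, direction, agreement; parameters go to a
#' sidecar JSON when `params_path` is given.
#' @param sig A [consensus_signature].
#' @param path TSV output path.
#' @param params_path Optional JSON path for the params record.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, params_path = NULL) {
  utils::write.table(sig$entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params_path)) {
    jsonlite::write_json(sig$params, params_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, params_path = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  params <- if (!is.null(params_path)) jsonlite::read_json(params_path, simplifyVector = TRUE) else list()
  consensus_signature(e, params)
}
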