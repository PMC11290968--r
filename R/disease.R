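#' Subgroup-differentiating disease signatures
#'
#' For every gene and subgroup, the log2 fold change of the subgroup's
#' central expression against the whole cohort. On log2-scale data the value
#' is a difference of centers; on linear-scale data it is
#' `log2((center_subgroup + eps) / (center_all + eps))` with a pseudocount
#' `eps` guarding against zeros. [subgroup_log2fc()] uses the median (the
#' "disease signature" variant); [subgroup_markers()] uses the mean (the
#' "subgroup marker" variant). Both require at least two subgroups with at
#' least two patients each.
#'
#' @param cohort An [expression_cohort].
#' @param eps Pseudocount for linear-scale data; default 1.
#' @return A `subgroup_signature`: list with `values` (genes x subgroups
#'   matrix of log2 fold changes) and `method` (`"median"` or `"mean"`).
#' @export
subgroup_log2fc <- function(cohort, eps = 1) {
  subgroup_center_fc(cohort, center = stats::median, method = "median", eps = eps)
}

#' @rdname subgroup_log2fc
#' @export
subgroup_markers <- function(cohort, eps = 1) {
  subgroup_center_fc(cohort, center = mean, method = "mean", eps = eps)
}

subgroup_center_fc <- function(cohort, center, method, eps) {
  stopifnot(inherits(cohort, "expression_cohort"))
  labs <- subgroup_levels(cohort)
  if (length(labs) < 2L) {
    abort_validation("need >= 2 subgroups, got %d", length(labs))
  }
  counts <- table(cohort$subgroup)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    abort_validation("subgroup(s) with < 2 patients: %s", paste(small, collapse = ", "))
  }
  expr <- cohort$expr$values
  center_all <- apply(expr, 1L, center)
  vals <- vapply(labs, function(lab) {
    sub <- expr[, cohort$subgroup == lab, drop = FALSE]
    center_sub <- apply(sub, 1L, center)
    if (cohort$scale == "log2") {
      center_sub - center_all
    } else {
      log2((center_sub + eps) / (center_all + eps))
    }
  }, numeric(nrow(expr)))
  vals <- matrix(vals, nrow = nrow(expr), dimnames = list(rownames(expr), labs))
  structure(list(values = vals, method = method), class = "subgroup_signature")
}

#' @export
print.subgroup_signature <- function(x, ...) {
  cat(sprintf("<subgroup_signature> %d genes x %d subgroups (%s-based)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Write per-subgroup disease signatures as TSV
#'
#' Writes one two-column TSV (gene, log2fc) per subgroup plus a combined
#' wide table.
#' @param sig A `subgroup_signature`.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_subgroup_signature <- function(sig, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (lab in colnames(sig$values)) {
    p <- file.path(dir, sprintf("disease_signature_%s.tsv", lab))
    utils::write.table(
      data.frame(gene = rownames(sig$values), log2fc = sig$values[, lab]),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  wide <- file.path(dir, "disease_signature_all.tsv")
  utils::write.table(
    data.frame(gene = rownames(sig$values), sig$values, check.names = FALSE),
    wide, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, wide))
}
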