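#' Spearman rank correlation with validation
#'
#' Average-rank (midrank) treatment of ties, computed on vectors of equal
#' length >= 3 with finite values. Errors on zero variance in either vector,
#' where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("x and y lengths differ (%d vs %d)", length(x), length(y))
  }
  if (length(x) < 3L) abort_validation("need >= 3 observations, got %d", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_validation("values must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("correlation undefined: zero variance", "sigdiscord_undefined_error")
  }
  stats::cor(x, y, method = "spearman")
}

# vectorized permutation null for a Spearman correlation: Pearson on midranks
# with the y-ranks permuted column-wise
spearman_perm_p <- function(x, y, n_perm, seed) {
  if (n_perm <= 0) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  with_seed(seed, {
    n <- length(ry)
    perms <- vapply(seq_len(n_perm), function(i) sample(ry), numeric(n))
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2)) * sqrt(sum((ry - mean(ry))^2))
    r_null <- as.numeric(crossprod(rxc, perms - mean(ry))) / denom
    # two-sided permutation p with the +1 correction
    (sum(abs(r_null) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  })
}

#' Score drug-subgroup discordance by Spearman correlation
#'
#' For each subgroup, aligns the genes shared between the drug's consensus
#' signature and the disease signature and computes the Spearman correlation
#' between consensus z values and subgroup log2 fold changes. A negative
#' correlation means the drug's transcriptional effect opposes the
#' subgroup's expression program — discordance — and predicts response. The
#' prediction is the bare sign rule `rho < 0`; a seeded gene-label
#' permutation p-value is reported alongside but does not gate it.
#'
#' @param drug_sig A [consensus_signature].
#' @param disease_sig A `subgroup_signature` ([subgroup_log2fc()] or
#'   [subgroup_markers()]).
#' @param n_perm Permutations for the two-sided p-value (default 10000;
#'   0 skips it).
#' @param seed Seed for the permutation null.
#' @return Data frame (class `response_score`) with columns `subgroup`,
#'   `rho`, `n_genes`, `perm_p`, `predicted_responsive`.
#' @export
discordance_score <- function(drug_sig, disease_sig, n_perm = 10000, seed = 1) {
  stopifnot(inherits(drug_sig, "consensus_signature"),
            inherits(disease_sig, "subgroup_signature"))
  shared <- intersect(signature_genes(drug_sig), rownames(disease_sig$values))
  if (length(shared) < 3L) {
    abort_validation(
      "only %d genes shared between drug signature (%d genes) and disease signature (%d genes); need >= 3",
      length(shared), length(signature_genes(drug_sig)), nrow(disease_sig$values))
  }
  z <- drug_sig$entries$consensus_z[match(shared, drug_sig$entries$gene)]
  out <- do.call(rbind, lapply(colnames(disease_sig$values), function(lab) {
    fc <- disease_sig$values[shared, lab]
    rho <- spearman_rho(z, fc)
    data.frame(subgroup = lab, rho = rho, n_genes = length(shared),
               perm_p = spearman_perm_p(z, fc, n_perm,
                                        seed = stage_seed(seed, lab)),
               predicted_responsive = rho < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("response_score", "data.frame")
  out
}

#' Rank signature genes by cell-line dependency
#'
#' Averages each gene's dependency score over the selected cell-line columns
#' and sorts ascending: the most negative mean (strongest dependency) first.
#' Genes absent from the dependency table are listed last with `NA` scores
#' and flagged.
#'
#' @param down_genes Character vector of genes to rank (typically the
#'   downregulated arm of a drug signature).
#' @param dependency A [matrix_table] of dependency scores
#'   (genes x cell lines); negative = required for survival.
#' @param lineage_cols Optional character vector of cell-line columns to
#'   average over (e.g. a tumor lineage); default all columns.
#' @return Data frame with columns `gene`, `mean_score`, `n_cell_lines`,
#'   `present`, ordered most-depended-on first.
#' @export
rank_dependencies <- function(down_genes, dependency, lineage_cols = NULL) {
  stopifnot(inherits(dependency, "matrix_table"))
  if (length(down_genes) == 0L) abort_validation("down_genes is empty")
  cols <- lineage_cols %||% col_ids(dependency)
  missing_cols <- setdiff(cols, col_ids(dependency))
  if (length(missing_cols)) {
    abort_validation("unknown cell-line columns: %s", paste(missing_cols, collapse = ", "))
  }
  present <- down_genes %in% row_ids(dependency)
  if (!any(present)) {
    abort_validation("none of the %d genes occur in the dependency table", length(down_genes))
  }
  score <- rep(NA_real_, length(down_genes))
  score[present] <- rowMeans(
    dependency$values[down_genes[present], cols, drop = FALSE], na.rm = TRUE)
  out <- data.frame(gene = down_genes, mean_score = score,
                    n_cell_lines = ifelse(present, length(cols), 0L),
                    present = present, stringsAsFactors = FALSE)
  # ascending mean score, absent genes last, id tie-break for determinism
  out <- out[order(!out$present, out$mean_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
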