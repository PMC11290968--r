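#' Mean gene-set expression per patient
#'
#' Unweighted mean over the listed genes that are present in the cohort;
#' genes missing from the matrix are dropped with a warning giving the
#' count.
#'
#' @param cohort An [expression_cohort].
#' @param genes Character vector of gene ids (>= 1 present).
#' @return Named numeric vector, one score per patient.
#' @export
geneset_score <- function(cohort, genes) {
  stopifnot(inherits(cohort, "expression_cohort"))
  present <- intersect(genes, row_ids(cohort$expr))
  if (length(present) == 0L) {
    abort_validation("none of the %d listed genes are in the cohort", length(genes))
  }
  n_missing <- length(setdiff(genes, present))
  if (n_missing > 0L) {
    warning(sprintf("%d of %d gene-set genes missing from cohort", n_missing, length(genes)),
            call. = FALSE)
  }
  colMeans(cohort$expr$values[present, , drop = FALSE], na.rm = TRUE)
}

#' Stratify patients into expression quartiles
#'
#' Patients are sorted ascending by score with ties broken by patient id
#' (stable and deterministic), then cut into four contiguous rank blocks
#' whose sizes differ by at most one. When `n` is not divisible by 4 the
#' extra patients go to the outer quartiles first, in the order Q1, Q4, Q2
#' (so n = 10 gives sizes 3, 2, 2, 3). The lowest block is Q1, the highest
#' Q4.
#'
#' @param score Named numeric vector of patient scores (>= 8 patients).
#' @return Named character vector mapping patient -> `"Q1"`..`"Q4"`.
#' @export
quartile_stratify <- function(score) {
  if (is.null(names(score))) abort_validation("score must be named by patient id")
  n <- length(score)
  if (n < 8L) abort_validation("need >= 8 patients, got %d", n)
  ord <- order(score, names(score))
  sizes <- rep(n %/% 4L, 4L)
  extra_order <- c(1L, 4L, 2L, 3L)
  r <- n %% 4L
  if (r > 0L) sizes[extra_order[seq_len(r)]] <- sizes[extra_order[seq_len(r)]] + 1L
  q <- rep(paste0("Q", 1:4), times = sizes)
  stats::setNames(q[order(ord)], names(score))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Classic chi-square statistic on one degree of freedom:
#' `(O_A - E_A)^2 / V`, with expected events and hypergeometric variance
#' summed over distinct event times and tied deaths counted together.
#'
#' @param groupA,groupB Data frames (or 2-column matrices) with columns
#'   `time` and `event` (1 = event, 0 = censored); times > 0.
#' @return List with `chi2` and `p` (chi-square, 1 df).
#' @export
logrank_test <- function(groupA, groupB) {
  ga <- as.data.frame(groupA); gb <- as.data.frame(groupB)
  names(ga)[1:2] <- names(gb)[1:2] <- c("time", "event")
  if (nrow(ga) == 0L || nrow(gb) == 0L) abort_validation("both groups must be nonempty")
  if (any(c(ga$time, gb$time) <= 0)) abort_validation("times must be > 0")
  if (!all(c(ga$event, gb$event) %in% c(0, 1))) abort_validation("event must be 0 or 1")
  if (sum(ga$event) + sum(gb$event) == 0) {
    abort("log-rank undefined: no events in either group", "sigdiscord_undefined_error")
  }
  time <- c(ga$time, gb$time)
  event <- c(ga$event, gb$event)
  grp <- factor(rep(c("A", "B"), c(nrow(ga), nrow(gb))))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- as.numeric(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Q4-vs-Q1 gene-set survival association
#'
#' Composes [geneset_score()], [quartile_stratify()] and [logrank_test()]:
#' patients are scored by mean expression of the gene set, stratified into
#' quartiles, and overall survival in the top quartile (Q4, highest
#' expression) is compared with the bottom quartile (Q1) by the log-rank
#' test; Q2/Q3 patients are excluded from the test. A single-gene list makes
#' this the per-gene outcome-predictor analysis.
#'
#' @param cohort An [expression_cohort] with survival data.
#' @param genes Character vector of gene ids.
#' @return List of class `survival_stratification` with `score`, `quartile`,
#'   `logrank_chi2`, `logrank_p`, `n_q1`, `n_q4`.
#' @export
q4_vs_q1_survival <- function(cohort, genes) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(cohort$survival)) abort_validation("cohort has no survival data")
  score <- geneset_score(cohort, genes)
  quartile <- quartile_stratify(score)
  surv <- cohort$survival
  pick <- function(q) {
    ids <- names(quartile)[quartile == q]
    s <- surv[surv$sample_id %in% ids, , drop = FALSE]
    data.frame(time = s$os_time, event = s$os_event)
  }
  g1 <- pick("Q1"); g4 <- pick("Q4")
  lr <- logrank_test(g4, g1)
  structure(
    list(score = score, quartile = quartile,
         logrank_chi2 = lr$chi2, logrank_p = lr$p,
         n_q1 = nrow(g1), n_q4 = nrow(g4)),
    class = "survival_stratification"
  )
}

#' @export
print.survival_stratification <- function(x, ...) {
  cat(sprintf("<survival_stratification> Q4 (n=%d) vs Q1 (n=%d): chi2=%.3f, p=%.4g\n",
              x$n_q4, x$n_q1, x$logrank_chi2, x$logrank_p))
  invisible(x)
}

#' Hierarchically cluster patients on a gene list
#'
#' Restricts the expression matrix to the listed genes, standardizes each
#' gene to mean 0 / sd 1 across patients (constant genes are dropped with a
#' warning), computes patient-patient distances and agglomerates. Returns
#' both the full merge tree and the cut at `k` clusters.
#'
#' @param cohort An [expression_cohort].
#' @param genes Character vector (>= 2 genes present after dropping
#'   constants).
#' @param k Number of clusters to cut at.
#' @param distance Distance metric passed to [stats::dist()]; default
#'   `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @return List of class `cluster_result` with `tree` (hclust), `labels`
#'   (named integer vector at `k`), `k`, `distance`, `linkage`,
#'   `genes_used`.
#' @export
cluster_patients <- function(cohort, genes, k, distance = "euclidean",
                             linkage = "complete") {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!is_count(k)) abort_validation("k must be a positive integer")
  present <- intersect(genes, row_ids(cohort$expr))
  if (length(present) < 2L) {
    abort_validation("need >= 2 listed genes in the cohort, found %d", length(present))
  }
  m <- cohort$expr$values[present, , drop = FALSE]
  if (ncol(m) < k) abort_validation("k = %d exceeds %d patients", k, ncol(m))
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s) before clustering", sum(sds == 0)),
            call. = FALSE)
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) < 2L) abort_validation("fewer than 2 non-constant genes remain")
  }
  zs <- t(scale(t(m)))
  d <- stats::dist(t(zs), method = distance)
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  structure(
    list(tree = tree, labels = labels, k = k,
         distance = distance, linkage = linkage, genes_used = rownames(m)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d patients, k=%d (%s/%s), %d genes\n",
              length(x$labels), x$k, x$distance, x$linkage, length(x$genes_used)))
  print(table(x$labels))
  invisible(x)
}
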