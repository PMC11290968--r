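surv_df <- function(time, event) data.frame(time = time, event = event)

test_that("geneset_score is the per-patient mean over present genes", {
  expr <- rbind(g1 = c(4, 8), g2 = c(6, 2), g3 = c(0, 0))
  colnames(expr) <- c("p1", "p2")
  co <- toy_cohort(expr, setNames(c("A", "B"), colnames(expr)))
  expect_equal(geneset_score(co, c("g1", "g2")), c(p1 = 5, p2 = 5))
  expect_equal(geneset_score(co, "g1"), c(p1 = 4, p2 = 8))
  expect_equal(geneset_score(co, c("g2", "g1")), geneset_score(co, c("g1", "g2")))
  expect_warning(s <- geneset_score(co, c("g1", "gX")), "1 of 2")
  expect_equal(s, c(p1 = 4, p2 = 8))
  expect_error(geneset_score(co, "gX"), "none of the")
})

test_that("quartile stratification cuts balanced contiguous rank blocks", {
  s8 <- setNames(1:8, sprintf("p%d", 1:8))
  q8 <- quartile_stratify(s8)
  expect_equal(unname(q8[c("p1", "p2")]), c("Q1", "Q1"))
  expect_equal(unname(q8[c("p7", "p8")]), c("Q4", "Q4"))

  # n = 10: outer quartiles take the remainder -> sizes 3,2,2,3
  s10 <- setNames(sample(100, 10), sprintf("p%02d", 1:10))
  q10 <- quartile_stratify(s10)
  expect_equal(as.vector(table(q10)[c("Q1", "Q2", "Q3", "Q4")]), c(3L, 2L, 2L, 3L))

  # sizes never differ by more than 1, any n
  for (n in 8:20) {
    q <- quartile_stratify(setNames(rnorm(n), sprintf("p%02d", 1:n)))
    expect_lte(diff(range(table(q))), 1)
  }

  # ties: assignment is by id order, deterministic
  tied <- setNames(rep(1, 8), sprintf("p%d", 8:1))
  qt <- quartile_stratify(tied)
  expect_equal(unname(qt[c("p1", "p2")]), c("Q1", "Q1"))
  expect_identical(qt, quartile_stratify(tied))

  # untied scores: Q1 max below Q4 min
  sc <- setNames(rnorm(17), sprintf("p%02d", 1:17))
  q <- quartile_stratify(sc)
  expect_lt(max(sc[q == "Q1"]), min(sc[q == "Q4"]))

  expect_error(quartile_stratify(setNames(1:7, paste0("p", 1:7))), ">= 8")
})

test_that("log-rank test reproduces hand-computed Mantel-Cox sums", {
  # symmetric groups: no signal
  lr0 <- logrank_test(surv_df(c(1, 2), c(1, 1)), surv_df(c(1, 2), c(1, 1)))
  expect_equal(lr0$chi2, 0)

  # hand computation: O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9
  lr <- logrank_test(surv_df(c(1, 2), c(1, 1)), surv_df(c(3, 4), c(1, 1)))
  expect_equal(lr$chi2, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-10)
  expect_equal(lr$chi2, 2.882, tolerance = 0.01)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))

  expect_error(logrank_test(surv_df(numeric(0), numeric(0)), surv_df(1, 1)),
               "nonempty")
  expect_error(logrank_test(surv_df(c(1, 2), c(0, 0)), surv_df(c(3, 4), c(0, 0))),
               "no events")
  expect_error(logrank_test(surv_df(c(0, 2), c(1, 1)), surv_df(c(3, 4), c(1, 1))),
               "> 0")
})

test_that("log-rank matches the explicit event-table oracle on random data", {
  set.seed(99)
  for (i in 1:500) {
    nA <- sample(3:15, 1); nB <- sample(3:15, 1)
    # integer times force ties across and within groups
    tA <- sample(1:8, nA, replace = TRUE); tB <- sample(1:8, nB, replace = TRUE)
    eA <- rbinom(nA, 1, 0.7); eB <- rbinom(nB, 1, 0.7)
    if (sum(eA) + sum(eB) == 0) next
    got <- logrank_test(surv_df(tA, eA), surv_df(tB, eB))
    want <- naive_logrank(tA, eA, tB, eB)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("Q4-vs-Q1 survival composes scoring, stratification and the test", {
  sim <- simulate_cohort(cohort_sim_spec(
    n_genes = 100, n_patients = 120,
    survival_geneset = sprintf("gene_%04d", 1:10),
    survival_hazard_ratio = 4, censor_rate = 0.1, seed = 42))
  res <- q4_vs_q1_survival(sim$cohort, sprintf("gene_%04d", 1:10))
  expect_s3_class(res, "survival_stratification")
  expect_equal(res$n_q1, 30)
  expect_equal(res$n_q4, 30)
  expect_lt(res$logrank_p, 0.05)
  # quartiles recomputed downstream agree with the generator's assignment
  expect_identical(unname(res$quartile), unname(sim$truth$survival_quartile))

  no_surv <- toy_cohort(matrix(rnorm(20), 2, 10,
                               dimnames = list(c("a", "b"), paste0("p", 1:10))),
                        setNames(rep("A", 10), paste0("p", 1:10)))
  expect_error(q4_vs_q1_survival(no_surv, "a"), "no survival")
})

test_that("clustering separates well-separated clouds and respects input order", {
  set.seed(7)
  n_half <- 15
  expr <- cbind(
    matrix(rnorm(20 * n_half, mean = 0), 20),
    matrix(rnorm(20 * n_half, mean = 12), 20)  # >= 10 sd away in every gene
  )
  dimnames(expr) <- list(sprintf("g%02d", 1:20), sprintf("p%02d", 1:(2 * n_half)))
  truth <- rep(1:2, each = n_half)
  co <- toy_cohort(expr, setNames(rep(c("A", "B"), each = n_half), colnames(expr)))
  cl <- cluster_patients(co, rownames(expr), k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_equal(length(cl$tree$height), 2 * n_half - 1)

  # k = n: every patient its own cluster
  cl_n <- cluster_patients(co, rownames(expr), k = 2 * n_half)
  expect_equal(length(unique(cl_n$labels)), 2 * n_half)

  # patient order only relabels clusters
  perm <- sample(2 * n_half)
  co_p <- toy_cohort(expr[, perm], setNames(rep(c("A", "B"), each = n_half),
                                            colnames(expr))[perm])
  cl_p <- cluster_patients(co_p, rownames(expr), k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels[colnames(expr)[perm]],
                                         cl_p$labels), 1)

  # constant genes are dropped with a warning; all-constant errors
  expr_c <- rbind(expr, gc1 = rep(5, 2 * n_half))
  co_c <- toy_cohort(expr_c, setNames(rep(c("A", "B"), each = n_half), colnames(expr)))
  expect_warning(cl_c <- cluster_patients(co_c, rownames(expr_c), k = 2), "constant")
  expect_false("gc1" %in% cl_c$genes_used)
  flat <- rbind(x = rep(1, 10), y = rep(2, 10))
  colnames(flat) <- paste0("p", 1:10)
  co_flat <- toy_cohort(flat, setNames(rep("A", 10), colnames(flat)))
  expect_error(suppressWarnings(cluster_patients(co_flat, c("x", "y"), k = 2)),
               "non-constant")
})

test_that("clustering on the drug signature separates the discordant subgroup", {
  sig <- consensus_signature(
    data.frame(gene = sprintf("gene_%04d", 1:20),
               consensus_z = c(seq(2, 6, length.out = 10), seq(-6, -2, length.out = 10)),
               direction = rep(c("up", "down"), each = 10), agreement = 1),
    params = list())
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_cohort(cohort_sim_spec(
      n_genes = 150, n_patients = 60, marker_log2fc = 2,
      discordant_subgroup = "G3", seed = s), drug_signature = sig)
    cl <- cluster_patients(sim$cohort, signature_genes(sig), k = 2)
    is_g3 <- as.integer(sim$cohort$subgroup == "G3")
    ari <- mclust::adjustedRandIndex(cl$labels, is_g3)
    hits <- hits + (ari >= 0.8)
  }
  expect_gte(hits / 10, 0.9)
})
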