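# Independent brute-force reimplementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with the package) so
# they check the implementation rather than mirror it.

# average-rank Spearman: midranks by explicit tie-group walk, then the
# Pearson sum formula
naive_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    o <- order(v)
    sv <- v[o]
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && sv[j + 1L] == sv[i]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# per-gene loop re-derivation of the consensus rule
naive_consensus <- function(z, tau, z_min) {
  out <- list()
  for (g in rownames(z)) {
    v <- z[g, ]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) next
    fu <- sum(obs >= z_min) / length(obs)
    fd <- sum(obs <= -z_min) / length(obs)
    up <- fu >= tau
    down <- fd >= tau
    if (up == down) next # neither, or direction-conflicted
    out[[g]] <- data.frame(gene = g, consensus_z = mean(obs),
                           direction = if (up) "up" else "down",
                           agreement = if (up) fu else fd,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(), consensus_z = numeric(),
                      direction = character(), agreement = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# explicit 2x2 hypergeometric table per distinct event time
naive_logrank <- function(timeA, eventA, timeB, eventB) {
  tt <- sort(unique(c(timeA[eventA == 1], timeB[eventB == 1])))
  OA <- sum(eventA)
  E <- 0; V <- 0
  for (t in tt) {
    nA <- sum(timeA >= t); nB <- sum(timeB >= t)
    dA <- sum(timeA == t & eventA == 1)
    dB <- sum(timeB == t & eventB == 1)
    d <- dA + dB; N <- nA + nB
    E <- E + d * nA / N
    if (N > 1) V <- V + d * (N - d) * nA * nB / (N^2 * (N - 1))
  }
  chi2 <- (OA - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# cell-by-cell HSA recomputation
naive_hsa <- function(surface) {
  excess <- c()
  for (i in seq_along(surface$doses_a)[-1L]) {
    for (j in seq_along(surface$doses_b)[-1L]) {
      expected <- max(surface$response[i, 1L], surface$response[1L, j])
      excess <- c(excess, surface$response[i, j] - expected)
    }
  }
  mean(excess)
}

# random small matrix_table for round-trip and permutation properties
random_table <- function(nr, nc, na_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(stats::rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("g%03d", seq_len(nr)),
                              sprintf("s%03d", seq_len(nc))))
  if (na_frac > 0) v[sample(length(v), ceiling(na_frac * length(v)))] <- NA
  matrix_table(v)
}

# small labeled cohort built directly (no simulator) for hand-value tests
toy_cohort <- function(expr, subgroup, survival = NULL, scale = "log2") {
  expression_cohort(matrix_table(expr), subgroup, survival = survival, scale = scale)
}

# write a dose-response long CSV from vectors
write_dr_csv <- function(path, dose_a, dose_b, response) {
  utils::write.csv(data.frame(dose_a = dose_a, dose_b = dose_b,
                              response_pct = response),
                   path, row.names = FALSE)
  path
}
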