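make_profiles <- function(z, lines = colnames(z), timepoint = "24 h") {
  matrix_table(z, col_meta = data.frame(cell_line = lines,
                                        timepoint = rep(timepoint, ncol(z)),
                                        stringsAsFactors = FALSE))
}

test_that("collapse_cell_lines filters the timepoint and averages replicates", {
  z <- matrix(c(1, 3, 2, 2, 5, 5), nrow = 1,
              dimnames = list("g1", paste0("c", 1:6)))
  profiles <- matrix_table(z, col_meta = data.frame(
    cell_line = c("A", "A", "B", "B", "A", "B"),
    timepoint = c("24 h", "24 h", "24 h", "24 h", "6 h", "6 h"),
    stringsAsFactors = FALSE))
  out <- collapse_cell_lines(profiles, "24 h")
  expect_equal(col_ids(out), c("A", "B"))
  expect_equal(out$values["g1", "A"], 2)   # mean(1, 3)
  expect_equal(out$values["g1", "B"], 2)
  expect_error(collapse_cell_lines(profiles, "48 h"), "48 h")

  # 18 cell lines x 2 replicates at 24 h -> 18 columns
  z2 <- matrix(rnorm(10 * 36), 10, 36,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:36)))
  p2 <- matrix_table(z2, col_meta = data.frame(
    cell_line = rep(sprintf("line%02d", 1:18), each = 2),
    timepoint = "24 h", stringsAsFactors = FALSE))
  expect_equal(ncol(collapse_cell_lines(p2, "24 h")$values), 18L)

  # single column in, same column out
  z3 <- matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  p3 <- make_profiles(z3, lines = "A")
  expect_equal(unname(collapse_cell_lines(p3, "24 h")$values[, 1]), c(1, 2, 3))
})

test_that("consensus retention follows the tau / z_min direction rule", {
  z <- rbind(
    gdown = c(-3, -2.5, -0.5, -4),   # 3/4 lines <= -2: retained down
    gweak = c(2.5, -2.5, 0.1, 0.2),  # 1/4 each direction: dropped
    gnull = c(1.5, -1.9, 0.5, 1.0),  # nothing passes |z| >= 2: dropped
    gup   = c(2.1, 2.2, 0.0, 2.3)    # 3/4 lines >= 2: retained up
  )
  colnames(z) <- paste0("L", 1:4)
  sig <- build_consensus(matrix_table(z), tau = 0.30, z_min = 2.0)
  expect_setequal(signature_genes(sig), c("gdown", "gup"))
  e <- sig$entries[sig$entries$gene == "gdown", ]
  expect_equal(e$direction, "down")
  expect_equal(e$agreement, 0.75)
  expect_equal(e$consensus_z, mean(c(-3, -2.5, -0.5, -4)))

  expect_error(build_consensus(matrix_table(z[, 1, drop = FALSE])), "2 cell lines")
  expect_error(build_consensus(matrix_table(z), tau = 0), "tau")
})

test_that("direction-conflicted genes are excluded and missing values are available-case", {
  # both directions meet tau = 0.5: conflicted, dropped
  z <- rbind(gconf = c(3, 3, -3, -3), gok = c(3, 3, 3, -1))
  colnames(z) <- paste0("L", 1:4)
  sig <- build_consensus(matrix_table(z), tau = 0.5, z_min = 2)
  expect_equal(signature_genes(sig), "gok")

  # NA line is ignored in both fraction and mean
  z2 <- rbind(g = c(4, 4, NA, 0))
  colnames(z2) <- paste0("L", 1:4)
  sig2 <- build_consensus(matrix_table(z2), tau = 0.5, z_min = 2)
  expect_equal(sig2$entries$agreement, 2 / 3)
  expect_equal(sig2$entries$consensus_z, mean(c(4, 4, 0)))
})

test_that("retention is monotone in tau among unconflicted genes, and permutation-invariant", {
  set.seed(31)
  for (i in 1:20) {
    z <- matrix(rnorm(60 * 8, sd = 2), 60, 8,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("L%d", 1:8)))
    mt <- matrix_table(z)
    genes_lo <- signature_genes(build_consensus(mt, tau = 0.25))
    genes_hi <- signature_genes(build_consensus(mt, tau = 0.60))
    # a gene retained at the stricter tau but not the looser one can only be
    # one that was direction-conflicted (both directions met the looser tau)
    escaped <- setdiff(genes_hi, genes_lo)
    if (length(escaped)) {
      fu <- rowMeans(z[escaped, , drop = FALSE] >= 2)
      fd <- rowMeans(z[escaped, , drop = FALSE] <= -2)
      expect_true(all(fu >= 0.25 & fd >= 0.25))
    }

    perm <- sample(ncol(z))
    sig_a <- build_consensus(mt)
    sig_b <- build_consensus(matrix_table(z[, perm]))
    expect_equal(sig_a$entries, sig_b$entries)
  }
})

test_that("build_consensus matches the naive per-gene loop oracle", {
  set.seed(77)
  for (i in 1:50) {
    z <- matrix(rnorm(50 * 8, sd = 2), 50, 8,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("L%d", 1:8)))
    z[sample(length(z), 20)] <- NA
    got <- build_consensus(matrix_table(z), tau = 0.3, z_min = 2)$entries
    want <- naive_consensus(z, tau = 0.3, z_min = 2)
    expect_equal(got, want)
  }
})

test_that("top_genes ranks by |consensus z| with lexicographic ties and universe filter", {
  sig <- consensus_signature(
    data.frame(gene = c("A", "B", "C"), consensus_z = c(3, -2, 1),
               direction = c("up", "down", "up"), agreement = c(1, 1, 1)),
    params = list())
  expect_equal(signature_genes(top_genes(sig, 2)), c("A", "B"))
  expect_equal(signature_genes(top_genes(sig, 10)), c("A", "B", "C"))

  tie <- consensus_signature(
    data.frame(gene = c("B", "A"), consensus_z = c(-2, 2),
               direction = c("down", "up"), agreement = c(1, 1)),
    params = list())
  expect_equal(signature_genes(top_genes(tie, 1)), "A")
  expect_equal(signature_genes(top_genes(sig, 2, universe = c("B", "C"))), c("B", "C"))
  expect_error(top_genes(sig, 0), "positive integer")
})

test_that("split_directions partitions every signature", {
  allup <- consensus_signature(
    data.frame(gene = c("A", "B"), consensus_z = c(2, 3),
               direction = "up", agreement = 1), params = list())
  expect_equal(split_directions(allup)$down, character(0))

  mix <- consensus_signature(
    data.frame(gene = c("A", "B", "C"), consensus_z = c(2, -3, -1),
               direction = c("up", "down", "down"), agreement = 1),
    params = list())
  expect_equal(split_directions(mix), list(up = "A", down = c("B", "C")))

  set.seed(5)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    genes <- sprintf("g%03d", sample(500, n))
    dirs <- sample(c("up", "down"), n, replace = TRUE)
    s <- consensus_signature(
      data.frame(gene = genes, consensus_z = ifelse(dirs == "up", 1, -1) * runif(n, 1, 5),
                 direction = dirs, agreement = runif(n, 0.3, 1)),
      params = list())
    parts <- split_directions(s)
    expect_setequal(c(parts$up, parts$down), genes)
    expect_length(intersect(parts$up, parts$down), 0)
  }
})

test_that("signatures round-trip through their TSV form", {
  sig <- consensus_signature(
    data.frame(gene = c("A", "B"), consensus_z = c(2.5, -3.25),
               direction = c("up", "down"), agreement = c(0.5, 0.75)),
    params = list(tau = 0.3, z_min = 2, timepoint = "24 h"))
  p <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, p, pp)
  back <- read_signature(p, pp)
  expect_equal(back$entries, sig$entries)
  expect_equal(back$params$tau, 0.3)
})
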